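# Comparison methods: massive-univariate GLM with Benjamini-Hochberg
# adjustment, and a voxelwise Bayesian multilevel model (BML) without
# spatial priors.

#' Massive-univariate GLM baseline
#'
#' Ordinary least squares independently at every location with t-based
#' inference, vectorized across locations.  This is the classical
#' mass-univariate fMRI baseline: no spatial pooling, no participant
#' deviations.
#'
#' @param formula model formula (response matrix on the left, or
#'   right-hand-side only with `images`).
#' @param data data frame of covariates.
#' @param images `N` by `V` response matrix.
#' @param level confidence level for the intervals (default 0.95).
#' @return Object of class `"bsir_glm"`: matrices `estimate`, `se`,
#'   `statistic`, `p_value`, `lower`, `upper` (`V` by `J+1`), residual
#'   degrees of freedom `df`.
#' @export
glm_voxelwise <- function(formula, data = NULL, images = NULL, level = 0.95) {
  des <- build_design(formula, data, images, standardize = FALSE)
  X <- des$X; Y <- des$Y
  N <- nrow(X); J1 <- ncol(X)
  if (N <= J1) stop("need more participants than design columns")
  XtXi <- tryCatch(solve(crossprod(X)), error = function(e)
    stop("rank-deficient design matrix"))
  coefs <- XtXi %*% crossprod(X, Y)              # J1 x V
  R <- Y - X %*% coefs
  df <- N - J1
  s2 <- colSums(R^2) / df                        # per-voxel residual variance
  se <- sqrt(outer(diag(XtXi), s2))              # J1 x V
  tt <- coefs / se
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  structure(list(estimate = t(coefs), se = t(se), statistic = t(tt),
                 p_value = t(p), lower = t(coefs - tq * se),
                 upper = t(coefs + tq * se), df = df, level = level,
                 covariate_names = colnames(X)),
            class = "bsir_glm")
}

#' @export
print.bsir_glm <- function(x, ...) {
  cat(sprintf("Voxelwise GLM: %d locations, %d coefficient(s), df = %d\n",
              nrow(x$estimate), ncol(x$estimate), x$df))
  invisible(x)
}

#' Benjamini-Hochberg adjustment with rejection mask
#'
#' Step-up BH adjusted p-values (monotone-enforced, via
#' [stats::p.adjust()]) and the rejections at FDR level `q`.
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` and logical `reject`.
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

#' Evidence maps for a voxelwise GLM via BH-adjusted p-values
#'
#' @param object a [glm_voxelwise()] fit.
#' @param q FDR level used for the adjustment (adjustment is across
#'   locations within each covariate).
#' @return `V` by `J+1` matrix of Es values \eqn{\pm(1 - p_{adj})}.
#' @export
glm_evidence <- function(object, q = 0.05) {
  stopifnot(inherits(object, "bsir_glm"))
  es <- object$p_value
  for (j in seq_len(ncol(es))) {
    adj <- bh_adjust(object$p_value[, j], q)$adjusted
    es[, j] <- evidence_from_pvalue(adj, object$estimate[, j])
  }
  es
}

#' Voxelwise Bayesian multilevel baseline (BML)
#'
#' Fits \deqn{y_i(s_v) = x_i^\top\alpha + x_i^\top\beta(s_v) + \eta_i +
#' \epsilon_i(s_v)} with voxel effects \eqn{\beta_j(s_v)} iid
#' \eqn{N(0, \sigma_{\beta j}^2)} across locations (no spatial
#' correlation), a scalar participant deviation \eqn{\eta_i}, iid noise,
#' and the same half-Cauchy/inverse-gamma hierarchy as the spatial model,
#' by conjugate Gibbs sampling.  This pools information across locations
#' through the shared variances only.
#'
#' @param formula,data,images as in [glm_voxelwise()].
#' @param control list: `n_chains` (3), `n_burn` (4000), `n_keep` (1000),
#'   `seed` (1), `A` (100), `fix_sig2_beta` (optional fixed value(s) of
#'   the voxel-effect variances, used to study the no-pooling and
#'   complete-pooling limits).
#' @return Object of class `"bsir_bml"` holding per-draw voxel effects
#'   \eqn{\alpha_j + \beta_j(s_v)} (`draws`: D x V x (J+1) array), global
#'   effect draws, and variance draws.
#' @export
bml_voxelwise <- function(formula, data = NULL, images = NULL,
                          control = list()) {
  des <- build_design(formula, data, images, standardize = FALSE)
  X <- des$X; Y <- des$Y
  N <- nrow(X); V <- ncol(Y); J1 <- ncol(X)
  n_chains <- control$n_chains %||% 3L
  n_burn <- control$n_burn %||% 4000L
  n_keep <- control$n_keep %||% 1000L
  seed <- control$seed %||% 1L
  A <- control$A %||% 100
  fixb <- control$fix_sig2_beta
  if (!is.null(fixb)) fixb <- rep_len(fixb, J1)
  XtX <- crossprod(X)
  D <- n_chains * n_keep
  eff <- array(NA_real_, c(D, V, J1))
  alpha_d <- matrix(NA_real_, D, J1)
  sig2_d <- matrix(NA_real_, D, 3 + J1)
  colnames(sig2_d) <- c("alpha", paste0("beta", seq_len(J1) - 1L), "eta", "eps")
  pos <- 0L
  overdisp <- c(0.5, 1, 2)
  for (ch in seq_len(n_chains)) {
    set.seed(as.integer(seed + 1000L * (ch - 1L)))
    sc <- overdisp[(ch - 1L) %% 3L + 1L]
    # warm start from voxelwise least squares
    co <- solve(XtX + diag(1e-8, J1), crossprod(X, Y))   # J1 x V
    alpha <- rowMeans(co)
    B <- t(co - alpha)                                   # V x J1
    eta <- numeric(N)
    s2e <- max(mean((Y - X %*% t(B) - drop(X %*% alpha))^2), 1e-6) * sc
    s2a <- max(mean(alpha^2), 0.1) * sc
    s2b <- pmax(colMeans(B^2), 0.01) * sc
    if (!is.null(fixb)) s2b <- fixb
    s2h <- 0.5 * s2e
    a_a <- a_h <- a_e <- A^2; a_b <- rep(A^2, J1)
    for (it in seq_len(n_burn + n_keep)) {
      # alpha | .
      R1 <- Y - tcrossprod(X, B) - eta
      P <- (V / s2e) * XtX + diag(1 / s2a, J1)
      U <- chol(P)
      alpha <- drop(chol_solve(U, crossprod(X, rowSums(R1)) / s2e) +
                    backsolve(U, stats::rnorm(J1)))
      # B | . : shared precision across voxels
      R2 <- Y - drop(X %*% alpha) - eta
      P <- XtX / s2e + diag(1 / s2b, J1)
      U <- chol(P)
      M <- chol_solve(U, crossprod(X, R2) / s2e)         # J1 x V
      B <- t(M + backsolve(U, matrix(stats::rnorm(J1 * V), J1, V)))
      # eta | .
      R3 <- Y - drop(X %*% alpha) - tcrossprod(X, B)
      prec <- V / s2e + 1 / s2h
      eta <- rowSums(R3) / s2e / prec + stats::rnorm(N) / sqrt(prec)
      # identifiability recentering (likelihood-invariant)
      em <- mean(eta); eta <- eta - em; alpha[1] <- alpha[1] + em
      bm <- colMeans(B); B <- sweep(B, 2, bm); alpha <- alpha + bm
      # variances and auxiliaries
      RR <- Y - drop(X %*% alpha) - tcrossprod(X, B) - eta
      s2a <- max(rinvgamma(1, 0.5 + J1 / 2, 1 / a_a + sum(alpha^2) / 2), 1e-12)
      if (is.null(fixb))
        s2b <- pmax(rinvgamma(J1, 0.5 + V / 2, 1 / a_b + colSums(B^2) / 2), 1e-12)
      s2h <- max(rinvgamma(1, 0.5 + N / 2, 1 / a_h + sum(eta^2) / 2), 1e-12)
      s2e <- max(rinvgamma(1, 0.5 + N * V / 2, 1 / a_e + sum(RR^2) / 2), 1e-12)
      a_a <- rinvgamma(1, 1, 1 / A^2 + 1 / s2a)
      a_b <- rinvgamma(J1, 1, 1 / A^2 + 1 / s2b)
      a_h <- rinvgamma(1, 1, 1 / A^2 + 1 / s2h)
      a_e <- rinvgamma(1, 1, 1 / A^2 + 1 / s2e)
      if (it > n_burn) {
        pos <- pos + 1L
        for (j in seq_len(J1)) eff[pos, , j] <- alpha[j] + B[, j]
        alpha_d[pos, ] <- alpha
        sig2_d[pos, ] <- c(s2a, s2b, s2h, s2e)
      }
    }
  }
  structure(list(draws = eff, alpha = alpha_d, sig2 = sig2_d,
                 covariate_names = colnames(X), n_chains = n_chains,
                 n_keep = n_keep, seed = seed),
            class = "bsir_bml")
}

#' @export
print.bsir_bml <- function(x, ...) {
  cat(sprintf("Voxelwise BML fit: %d locations, %d coefficient(s), %d draws\n",
              dim(x$draws)[2], dim(x$draws)[3], dim(x$draws)[1]))
  invisible(x)
}

#' Summarize a voxelwise BML fit
#'
#' @param object a [bml_voxelwise()] fit.
#' @param level credible level (default 0.95).
#' @param threshold,mode activation rule, as in [summary.bsir()].
#' @param ... unused.
#' @return A `"summary.bsir"`-style object (per-covariate data frames with
#'   `mean`, `sd`, `lower`, `upper`, `p_plus`, `es`, `active`).
#' @export
summary.bsir_bml <- function(object, level = 0.95, threshold = 0.95,
                             mode = c("two-sided", "positive"), ...) {
  mode <- match.arg(mode)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  J1 <- dim(object$draws)[3]
  effects <- vector("list", J1)
  names(effects) <- object$covariate_names
  for (j in seq_len(J1)) {
    E <- object$draws[, , j]
    m <- colMeans(E)
    s <- sqrt(pmax(colMeans(E^2) - m^2, 0)) * sqrt(nrow(E) / (nrow(E) - 1))
    qq <- apply(E, 2, stats::quantile, probs = qs, names = FALSE)
    effects[[j]] <- summarize_one(m, s, qq[1, ], qq[2, ], colMeans(E > 0),
                                  threshold, mode)
  }
  structure(list(effects = effects, level = level, include_global = TRUE,
                 threshold = threshold, mode = mode, engine = "bml",
                 rhat = NA_real_, covariate_names = object$covariate_names),
            class = "summary.bsir")
}
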
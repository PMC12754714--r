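#' Fit a Bayesian spatial image-on-scalar regression model
#'
#' Fits the hierarchical model
#' \deqn{y_i(s_v) = \sum_{j=0}^J x_{ij}\,\alpha_j +
#'   \sum_{j=0}^J x_{ij}\,\beta_j(s_v) + \eta_i(s_v) + \epsilon_i(s_v)}
#' in which the spatially varying covariate effects \eqn{\beta_j}, the
#' participant deviations \eqn{\eta_i} and the noise field all carry
#' Gaussian-process priors with a shared Matern kernel, and the standard
#' deviations carry half-Cauchy priors (scale `A`) via the usual
#' inverse-gamma mixture.  The GP fields are reduced to `L` (and `L_eta`)
#' Karhunen-Loeve basis coefficients through the Nystrom approximation,
#' the responses are projected onto that basis, and the resulting
#' low-dimensional conjugate model is fitted either by coordinate-ascent
#' variational inference (`engine = "vi"`, fast deterministic
#' approximation) or by a multi-chain conjugate Gibbs sampler
#' (`engine = "gibbs"`).
#'
#' Identifiability of the decomposition into global plus spatially varying
#' effects follows the constraints \eqn{\sum_i \eta_i(s_v) = 0} and
#' \eqn{\sum_v \beta_j(s_v) = 0}, enforced by exact likelihood-invariant
#' recentering (per iteration in the Gibbs sampler; once at convergence
#' for the variational fit).
#'
#' @param formula model formula.  The response may be given on the left
#'   (`Y ~ gain`, with `Y` an `N` by `V` matrix) or via `images` with a
#'   right-hand-side-only formula (`~ gain`).  An intercept is required.
#' @param data data frame of participant covariates.
#' @param images `N` by `V` response matrix when `formula` has no left side.
#' @param domain a [spatial_domain()] with `V` locations (not needed when
#'   `basis` is supplied).
#' @param kernel a [matern_kernel()].
#' @param L number of basis functions; choose with [choose_L()].
#' @param L_eta participant-deviation basis size, default `ceiling(0.1 L)`.
#' @param basis optionally a prebuilt [lowrank_basis()] (overrides
#'   `domain`/`kernel`/`L`/`L_eta`).
#' @param engine `"vi"` or `"gibbs"`.
#' @param standardize center and scale non-intercept covariates; effects
#'   are then per standard deviation of the covariate.
#' @param seed integer seed; fits are deterministic given the seed.
#' @param control engine options.  Gibbs: `n_chains` (3), `n_burn` (4000),
#'   `n_keep` (1000), `thin` (1), `store_eta` (TRUE), `rhat_threshold`
#'   (1.1).  VI: `max_iter` (500), `rel_tol` (1e-8).  Both: `A` (100).
#' @param keep_images keep the response matrix in the fit (needed by
#'   [posterior_predictive()], `fitted()` and `residuals()`).
#' @return An object of class `"bsir"`; see [summary.bsir()],
#'   [coef.bsir()], [predict.bsir()], [posterior_predictive()].
#' @examples
#' truth <- sim_truth(sim_mask(400, seed = 1), sigma_eps = 2, snr = 0.3, seed = 1)
#' d <- sim_dataset(truth, N = 30, seed = 1)
#' fit <- bsir(~ x, data = d$data, images = d$Y, domain = truth$domain,
#'             kernel = matern_kernel(0.3), L = 40, engine = "vi",
#'             standardize = FALSE, seed = 1)
#' fit
#' @export
bsir <- function(formula, data = NULL, images = NULL, domain = NULL,
                 kernel = matern_kernel(0.3), L = 100, L_eta = NULL,
                 basis = NULL, engine = c("vi", "gibbs"),
                 standardize = TRUE, seed = 1L, control = list(),
                 keep_images = TRUE) {
  engine <- match.arg(engine)
  cl <- match.call()
  des <- build_design(formula, data, images, standardize)
  Y <- des$Y
  if (is.null(basis)) {
    if (is.null(domain)) stop("supply either 'domain' or a prebuilt 'basis'")
    basis <- lowrank_basis(domain, kernel, L = L, L_eta = L_eta,
                           seed = seed)
  }
  td <- make_tdata(Y, des$X, basis)
  fit <- list(call = cl, formula = formula, engine = engine,
              covariate_names = colnames(des$X),
              X = des$X, x_center = des$center, x_scale = des$scale,
              basis = basis, td = td, seed = as.integer(seed),
              Y = if (keep_images) Y else NULL)
  if (engine == "gibbs") {
    config <- utils::modifyList(list(seed = seed), control)
    draws <- run_gibbs(td, basis$g, config)
    fit$draws <- draws
    fit$rhat <- draws$rhat
    thr <- control$rhat_threshold %||% 1.1
    if (is.finite(fit$rhat %||% NA_real_) && !is.na(fit$rhat) && fit$rhat > thr)
      warning(sprintf("R-hat on the conditional log-likelihood is %.3f (> %.2f); chains may not have converged",
                      fit$rhat, thr))
  } else {
    set.seed(as.integer(seed))   # VI is deterministic; seed fixed for parity
    vi <- run_cavi(td, config = control)
    vi$q <- recenter_q(vi$q, td, basis$g)
    fit$vi <- vi
  }
  class(fit) <- "bsir"
  fit
}

# Evaluate formula/data/images into Y, X (+ standardization info).
build_design <- function(formula, data, images, standardize) {
  if (length(formula) == 3L) {
    Y <- eval(formula[[2L]], envir = data %||% environment(formula),
              enclos = environment(formula))
    rhs <- formula[-2L]
  } else {
    if (is.null(images)) stop("supply 'images' when the formula has no response")
    Y <- images
    rhs <- formula
  }
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("missing image values are not supported")
  mf <- stats::model.frame(rhs, data = data %||% parent.frame(),
                           na.action = stats::na.fail)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (!"(Intercept)" %in% colnames(X)) stop("the model requires an intercept")
  if (nrow(X) != nrow(Y)) stop("covariates and images disagree on N")
  if (nrow(Y) < 2L) stop("need at least two participants")
  center <- scale <- NULL
  if (standardize && ncol(X) > 1L) {
    idx <- which(colnames(X) != "(Intercept)")
    center <- colMeans(X[, idx, drop = FALSE])
    scale <- apply(X[, idx, drop = FALSE], 2, stats::sd)
    if (any(scale == 0)) stop("constant covariate cannot be standardized")
    X[, idx] <- sweep(sweep(X[, idx, drop = FALSE], 2, center), 2, scale, "/")
  }
  list(Y = Y, X = X, center = center, scale = scale, terms = attr(mf, "terms"))
}

#' @export
print.bsir <- function(x, ...) {
  td <- x$td
  cat("Bayesian image-on-scalar regression fit\n")
  cat(sprintf("  %d participants, %d locations, %d covariate(s) + intercept\n",
              td$N, x$basis$domain$V, td$J))
  cat(sprintf("  basis: L = %d, L_eta = %d; kernel length scale %.3g\n",
              td$L, td$L_eta, x$basis$kernel$length_scale))
  if (x$engine == "gibbs") {
    cat(sprintf("  engine: Gibbs, %d chain(s) x %d kept draws; R-hat(loglik) = %s\n",
                x$draws$n_chains, x$draws$n_keep,
                ifelse(is.na(x$rhat), "NA", sprintf("%.3f", x$rhat))))
  } else {
    cat(sprintf("  engine: VI, %d sweeps, ELBO %.4f (%s)\n",
                x$vi$iterations, x$vi$elbo,
                ifelse(x$vi$converged, "converged", "max_iter reached")))
  }
  invisible(x)
}

#' Posterior mean voxel-level effect maps
#'
#' @param object a fitted [bsir()] model.
#' @param include_global include the global effect \eqn{\alpha_j} in each
#'   map (the voxel-level effect of interest is \eqn{\alpha_j + \beta_j(s_v)}).
#' @param ... unused.
#' @return `V` by `J+1` matrix, one column per covariate.
#' @export
coef.bsir <- function(object, include_global = TRUE, ...) {
  ig <- as.numeric(include_global)
  if (object$engine == "vi") {
    q <- object$vi$q
    out <- object$basis$B %*% t(q$M_b) + rep(1, nrow(object$basis$B)) %o% (ig * q$m_a)
  } else {
    a <- colMeans(stack_draws(object$draws, "alpha"))
    tb <- stack_draws(object$draws, "theta_beta")
    tbm <- apply(tb, c(2, 3), mean)
    out <- object$basis$B %*% t(tbm) + rep(1, nrow(object$basis$B)) %o% (ig * a)
  }
  colnames(out) <- object$covariate_names
  out
}

#' Predict images for new participants
#'
#' Returns \eqn{x^\top\alpha\,1_V + x^\top\theta_\beta\Lambda^{1/2}\Psi^\top}
#' per design row, using posterior means.  Participant deviations are
#' included only for in-sample participants (`include_eta = TRUE` with
#' `newdata = NULL`); new participants get \eqn{\eta = 0}.
#'
#' @param object a fitted [bsir()] model.
#' @param newdata data frame of covariates; `NULL` for in-sample designs.
#' @param include_eta add posterior-mean participant deviations
#'   (in-sample only).
#' @param ... unused.
#' @return `nrow(newdata)` by `V` matrix of predicted images.
#' @export
predict.bsir <- function(object, newdata = NULL, include_eta = FALSE, ...) {
  if (is.null(newdata)) {
    X_new <- object$X
  } else {
    if (include_eta) stop("include_eta applies to in-sample participants only")
    rhs <- if (length(object$formula) == 3L) object$formula[-2L] else object$formula
    X_new <- stats::model.matrix(rhs, stats::model.frame(rhs, newdata))
    if (!is.null(object$x_center)) {
      idx <- which(colnames(X_new) != "(Intercept)")
      X_new[, idx] <- sweep(sweep(X_new[, idx, drop = FALSE], 2,
                                  object$x_center), 2, object$x_scale, "/")
    }
  }
  pm <- posterior_means(object)
  te <- NULL
  if (include_eta) te <- pm$theta_eta
  predict_images(pm$alpha, pm$theta_beta, X_new, object$basis, theta_eta = te)
}

# Posterior means of all coefficient blocks, either engine.
posterior_means <- function(object) {
  if (object$engine == "vi") {
    q <- object$vi$q
    list(alpha = q$m_a, theta_beta = q$M_b, theta_eta = q$M_e)
  } else {
    te <- stack_draws(object$draws, "theta_eta")
    list(alpha = colMeans(stack_draws(object$draws, "alpha")),
         theta_beta = apply(stack_draws(object$draws, "theta_beta"), c(2, 3), mean),
         theta_eta = if (!is.null(te)) apply(te, c(2, 3), mean))
  }
}

#' @export
fitted.bsir <- function(object, ...) predict(object, include_eta = TRUE)

#' @export
residuals.bsir <- function(object, ...) {
  if (is.null(object$Y)) stop("fit was run with keep_images = FALSE")
  object$Y - fitted(object)
}

#' Draw replicate datasets from the posterior predictive distribution
#'
#' @param object a fitted [bsir()] model.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return `N` by `V` by `nsim` array of replicated images.
#' @export
simulate.bsir <- function(object, nsim = 1, seed = NULL, ...) {
  if (nsim < 1) stop("nsim must be at least 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  N <- object$td$N; V <- object$basis$domain$V
  out <- array(NA_real_, c(N, V, nsim))
  for (r in seq_len(nsim)) out[, , r] <- ppd_replicate(object)
  out
}

# One posterior-predictive replicate: sample parameters from the
# posterior, then data from the likelihood (GP noise via the low-rank
# kernel representation).
ppd_replicate <- function(object) {
  b <- object$basis
  if (object$engine == "vi") {
    q <- object$vi$q
    J1 <- length(q$m_a)
    a <- drop(q$m_a + t(chol(q$S_a + diag(1e-12, J1))) %*% stats::rnorm(J1))
    tb <- q$M_b + t(chol(q$S_b + diag(1e-12, J1))) %*%
      matrix(stats::rnorm(J1 * object$td$L), J1, object$td$L)
    te <- q$M_e + matrix(stats::rnorm(object$td$N * object$td$L_eta),
                         object$td$N) %*% chol(q$S_eta + diag(1e-12, object$td$L_eta))
    s2e <- rinvgamma(1, q$sig$eps$shape, q$sig$eps$rate)
  } else {
    D <- object$draws$n_chains * object$draws$n_keep
    k <- sample.int(D, 1)
    a <- stack_draws(object$draws, "alpha")[k, ]
    tb <- stack_draws(object$draws, "theta_beta")[k, , , drop = TRUE]
    if (is.null(dim(tb))) tb <- matrix(tb, nrow = 1)
    tear <- stack_draws(object$draws, "theta_eta")
    if (is.null(tear))
      stop("posterior predictive draws need store_eta = TRUE in the Gibbs control")
    te <- tear[k, , , drop = TRUE]
    if (is.null(dim(te))) te <- matrix(te, ncol = object$td$L_eta)
    s2e <- stack_draws(object$draws, "sig2")[k, "eps"]
  }
  mu <- predict_images(a, tb, object$X, b, theta_eta = te)
  eps <- matrix(stats::rnorm(object$td$N * ncol(b$B)), object$td$N) %*% t(b$B)
  mu + sqrt(s2e) * eps
}

#' Plot posterior effect maps of a 2-D fit
#'
#' @param x a fitted [bsir()] model on a 2-D domain.
#' @param which covariate index (1 = intercept).
#' @param what `"mean"` or `"es"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.bsir <- function(x, which = 1L, what = c("mean", "es"), ...) {
  what <- match.arg(what)
  dom <- x$basis$domain
  if (dom$d != 2L) stop("plotting is implemented for 2-D domains")
  val <- if (what == "mean") coef(x)[, which]
  else summary(x)$effects[[which]]$es
  plot_domain_map(dom, val, main = sprintf("%s (%s)",
                  x$covariate_names[which], what), ...)
}

# Render a per-voxel vector on the source grid (2-D domains).
plot_domain_map <- function(dom, val, ...) {
  if (!is.null(dom$grid)) {
    img <- matrix(NA_real_, dom$grid$dim[1], dom$grid$dim[2])
    img[dom$grid$mask_idx] <- val
    graphics::image(img, useRaster = TRUE, ...)
  } else {
    cr <- dom$coords_raw
    graphics::plot(cr[, 1], cr[, 2], col = grDevices::hcl.colors(64)[
      cut(val, 64, labels = FALSE)], pch = 15, cex = 0.6, ...)
  }
  invisible(NULL)
}
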
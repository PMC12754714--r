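# Posterior summaries: voxel effect maps, P+, the Es evidence measure,
# activation masks, and posterior predictive checks.

#' Summarize voxel-level effects of a fitted model
#'
#' For each covariate `j` and location `v`, summarizes the posterior of
#' the voxel-level effect \eqn{\alpha_j + \beta_j(s_v)} (or \eqn{\beta_j(s_v)}
#' alone with `include_global = FALSE`): posterior mean, SD, equal-tailed
#' `level` credible interval, the posterior probability of a positive
#' effect \eqn{P_+}, the evidence measure \eqn{E_s = 2(P_+ - 0.5)}, and the
#' activation mask at `|Es| > threshold` (two-sided default; `"positive"`
#' thresholds \eqn{E_s > } `threshold`).
#'
#' Variational fits use the Gaussian marginals of the mean-field factors;
#' Gibbs fits use empirical draws (at least 50 kept draws are required).
#'
#' @param object a fitted [bsir()] model.
#' @param level credible level for the intervals (default 0.95).
#' @param include_global include \eqn{\alpha_j} in the voxel effect.
#' @param threshold evidence threshold for the activation mask.
#' @param mode `"two-sided"` or `"positive"` activation rule.
#' @param ... unused.
#' @return Object of class `"summary.bsir"`: a list with one element per
#'   covariate, each a data frame with columns `mean`, `sd`, `lower`,
#'   `upper`, `p_plus`, `es`, `active`.
#' @export
summary.bsir <- function(object, level = 0.95, include_global = TRUE,
                         threshold = 0.95, mode = c("two-sided", "positive"),
                         ...) {
  mode <- match.arg(mode)
  ig <- as.numeric(include_global)
  B <- object$basis$B
  J1 <- object$td$J + 1L
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  effects <- vector("list", J1)
  names(effects) <- object$covariate_names
  if (object$engine == "vi") {
    q <- object$vi$q
    b2 <- rowSums(B^2)
    for (j in seq_len(J1)) {
      m <- drop(ig * q$m_a[j] + B %*% q$M_b[j, ])
      v <- ig * q$S_a[j, j] + q$S_b[j, j] * b2
      s <- sqrt(pmax(v, 0))
      p_plus <- stats::pnorm(0, m, pmax(s, .Machine$double.xmin), lower.tail = FALSE)
      effects[[j]] <- summarize_one(m, s, m + stats::qnorm(qs[1]) * s,
                                    m + stats::qnorm(qs[2]) * s,
                                    p_plus, threshold, mode)
    }
  } else {
    a <- stack_draws(object$draws, "alpha")
    tb <- stack_draws(object$draws, "theta_beta")
    D <- nrow(a)
    if (D < 50L) stop("too few posterior draws (< 50) for summaries")
    V <- nrow(B)
    for (j in seq_len(J1)) {
      m <- sdv <- lo <- up <- pp <- numeric(V)
      tbj <- tb[, j, , drop = TRUE]
      if (is.null(dim(tbj))) tbj <- matrix(tbj, nrow = D)
      for (start in seq(1, V, by = 1024L)) {
        idx <- start:min(start + 1023L, V)
        E <- ig * a[, j] + tbj %*% t(B[idx, , drop = FALSE])  # D x chunk
        m[idx] <- colMeans(E)
        sdv[idx] <- sqrt(colMeans(E^2) - colMeans(E)^2) * sqrt(D / (D - 1))
        qq <- apply(E, 2, stats::quantile, probs = qs, names = FALSE)
        lo[idx] <- qq[1, ]; up[idx] <- qq[2, ]
        pp[idx] <- colMeans(E > 0)
      }
      effects[[j]] <- summarize_one(m, sdv, lo, up, pp, threshold, mode)
    }
  }
  structure(list(effects = effects, level = level,
                 include_global = include_global, threshold = threshold,
                 mode = mode, engine = object$engine,
                 rhat = object$rhat %||% NA_real_,
                 covariate_names = object$covariate_names),
            class = "summary.bsir")
}

summarize_one <- function(m, s, lo, up, p_plus, threshold, mode) {
  es <- 2 * (p_plus - 0.5)
  data.frame(mean = m, sd = s, lower = lo, upper = up,
             p_plus = p_plus, es = es,
             active = threshold_active(es, threshold, mode))
}

#' @export
print.summary.bsir <- function(x, ...) {
  cat(sprintf("Voxel-level effect summaries (%s engine, %.0f%% intervals, |Es| > %.2f %s)\n",
              x$engine, 100 * x$level, x$threshold, x$mode))
  for (j in seq_along(x$effects)) {
    e <- x$effects[[j]]
    cat(sprintf("  %-12s mean range [%.3f, %.3f], %d/%d active locations\n",
                x$covariate_names[j], min(e$mean), max(e$mean),
                sum(e$active), nrow(e)))
  }
  if (!is.na(x$rhat)) cat(sprintf("  R-hat (conditional log-likelihood): %.3f\n", x$rhat))
  invisible(x)
}

#' Activation mask from an evidence map
#'
#' @param es vector of evidence values in `[-1, 1]`.
#' @param threshold evidence cutoff (default 0.95).
#' @param mode `"two-sided"` declares `|Es| > threshold`; `"positive"`
#'   declares `Es > threshold`.
#' @return Logical vector.
#' @export
threshold_active <- function(es, threshold = 0.95,
                             mode = c("two-sided", "positive")) {
  mode <- match.arg(mode)
  if (mode == "two-sided") abs(es) > threshold else es > threshold
}

#' Convert adjusted p-values to the Es evidence scale
#'
#' Frequentist results enter the unified evidence measure as
#' \eqn{E_s = 1 - p} for positive estimates and \eqn{E_s = -(1 - p)} for
#' negative ones.
#'
#' @param p vector of (adjusted) p-values in `[0, 1]`.
#' @param sign vector of effect signs (`+1`/`-1`, or any numeric whose sign
#'   is used).
#' @return Evidence values in `[-1, 1]`.
#' @export
evidence_from_pvalue <- function(p, sign) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  ifelse(sign >= 0, 1 - p, -(1 - p))
}

#' Posterior predictive check of a fitted model
#'
#' Draws `n_rep` replicate datasets from the posterior predictive
#' distribution (parameters sampled from the posterior, data from the
#' likelihood with GP noise generated through the low-rank kernel) and
#' summarizes the pooled value distribution of each replicate on a common
#' 512-point grid, with kernel density estimates at a shared Silverman
#' bandwidth, for comparison against the observed data density.
#'
#' @param object a fitted [bsir()] model (with `keep_images = TRUE`).
#' @param n_rep number of replicates (default 150).
#' @param seed integer seed.
#' @return Object of class `"bsir_ppc"`: `grid`, `obs_density`,
#'   `rep_density` (`n_rep` by 512), and `envelope_coverage`, the fraction
#'   of grid points at which the observed density lies inside the pointwise
#'   replicate envelope.
#' @export
posterior_predictive <- function(object, n_rep = 150L, seed = 1L) {
  if (n_rep < 1L) stop("n_rep must be at least 1")
  if (is.null(object$Y)) stop("fit was run with keep_images = FALSE")
  set.seed(as.integer(seed))
  obs <- as.vector(object$Y)
  bw <- stats::bw.nrd0(if (length(obs) > 50000L) sample(obs, 50000L) else obs)
  rng <- range(obs) + c(-3, 3) * bw
  dens <- function(x) stats::density(x, bw = bw, from = rng[1], to = rng[2],
                                     n = 512L)$y
  obs_d <- dens(obs)
  rep_d <- matrix(NA_real_, n_rep, 512L)
  for (r in seq_len(n_rep)) rep_d[r, ] <- dens(as.vector(ppd_replicate(object)))
  env_lo <- apply(rep_d, 2, min); env_hi <- apply(rep_d, 2, max)
  structure(list(grid = seq(rng[1], rng[2], length.out = 512L),
                 obs_density = obs_d, rep_density = rep_d,
                 envelope_coverage = mean(obs_d >= env_lo & obs_d <= env_hi),
                 n_rep = n_rep),
            class = "bsir_ppc")
}

#' @export
print.bsir_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive check: %d replicates; observed density inside the replicate envelope at %.1f%% of grid points\n",
              x$n_rep, 100 * x$envelope_coverage))
  invisible(x)
}

#' @export
plot.bsir_ppc <- function(x, ...) {
  graphics::matplot(x$grid, t(x$rep_density), type = "l", lty = 1,
                    col = grDevices::adjustcolor("goldenrod", 0.25),
                    xlab = "value", ylab = "density", ...)
  graphics::lines(x$grid, x$obs_density, col = "black", lwd = 2)
  invisible(NULL)
}
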
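# Evaluation metrics and the replicated simulation study.

#' Estimation and selection metrics against a known truth
#'
#' @param estimate matrix (or vector) of estimated voxel effects.
#' @param truth matching matrix of true effects.
#' @param es matching matrix of evidence values; activation is declared at
#'   `|Es| > es_threshold`.
#' @param lower,upper matching interval bounds (optional; `coverage` is
#'   `NA` without them).
#' @param active_truth logical matrix of truly nonzero locations; default
#'   `truth != 0` (the generator places exact zeros outside the active
#'   regions).
#' @param es_threshold evidence threshold (default 0.95).
#' @return List with `mse`, `tpr`, `fdr`, `coverage`, and
#'   `no_declarations` (TRUE when nothing was declared, in which case the
#'   FDR is defined as 0).
#' @export
effect_metrics <- function(estimate, truth, es, lower = NULL, upper = NULL,
                           active_truth = NULL, es_threshold = 0.95) {
  estimate <- as.matrix(estimate); truth <- as.matrix(truth)
  es <- as.matrix(es)
  if (!all(dim(estimate) == dim(truth)) || !all(dim(es) == dim(truth)))
    stop("shape mismatch between estimates, truth and evidence")
  if (is.null(active_truth)) active_truth <- truth != 0
  declared <- abs(es) > es_threshold
  tp <- sum(declared & active_truth)
  fp <- sum(declared & !active_truth)
  fn <- sum(!declared & active_truth)
  cov <- NA_real_
  if (!is.null(lower) && !is.null(upper))
    cov <- mean(lower <= truth & truth <= upper)
  list(mse = mean((estimate - truth)^2),
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fdr = fp / max(tp + fp, 1),
       coverage = cov,
       no_declarations = (tp + fp) == 0L)
}

# Fit one method on one simulated dataset and return its metrics.
sim_fit_method <- function(method, d, truth, L, basis, control, seed) {
  tr_eff <- truth$beta                      # V x 2 true voxel effects (alpha = 0)
  act <- truth$active
  if (method == "glm") {
    g <- glm_voxelwise(~ x, data = d$data, images = d$Y)
    es <- glm_evidence(g)
    return(effect_metrics(g$estimate, tr_eff, es, g$lower, g$upper, act))
  }
  if (method == "bml") {
    b <- bml_voxelwise(~ x, data = d$data, images = d$Y,
                       control = utils::modifyList(
                         list(n_chains = 1L, n_burn = 400L, n_keep = 400L,
                              seed = seed), control$bml %||% list()))
    s <- summary(b)
    est <- vapply(s$effects, `[[`, numeric(nrow(tr_eff)), "mean")
    es <- vapply(s$effects, `[[`, numeric(nrow(tr_eff)), "es")
    lo <- vapply(s$effects, `[[`, numeric(nrow(tr_eff)), "lower")
    up <- vapply(s$effects, `[[`, numeric(nrow(tr_eff)), "upper")
    return(effect_metrics(est, tr_eff, es, lo, up, act))
  }
  engine <- if (method == "gibbs") "gibbs" else "vi"
  ctl <- if (engine == "gibbs")
    utils::modifyList(list(n_chains = 1L, n_burn = 400L, n_keep = 400L),
                      control$gibbs %||% list())
  else control$vi %||% list()
  f <- bsir(~ x, data = d$data, images = d$Y, basis = basis,
            engine = engine, standardize = FALSE, seed = seed,
            control = ctl, keep_images = FALSE)
  s <- summary(f)
  est <- vapply(s$effects, `[[`, numeric(nrow(tr_eff)), "mean")
  es <- vapply(s$effects, `[[`, numeric(nrow(tr_eff)), "es")
  lo <- vapply(s$effects, `[[`, numeric(nrow(tr_eff)), "lower")
  up <- vapply(s$effects, `[[`, numeric(nrow(tr_eff)), "upper")
  effect_metrics(est, tr_eff, es, lo, up, act)
}

#' Replicated simulation study over scenario grid
#'
#' Reproduces the two-region sparse-activation simulation design over a
#' grid of sample sizes and noise levels: for each scenario and replicate
#' a dataset is generated from the model, each requested method is fitted,
#' and estimation/selection metrics are aggregated (mean and SD over
#' replicates).  Fully seeded: replicate `r` of scenario `s` uses seed
#' `seed + 1000 * s + r`.
#'
#' @param scenarios data frame with columns `N` and `sigma_eps`; default
#'   the four-scenario grid `N` in (50, 200) by `sigma_eps` in (2, 5),
#'   with SNR 0.3 at `sigma_eps = 2` and 0.05 at `sigma_eps = 5`.
#' @param n_reps replicates per scenario.
#' @param methods subset of `"glm"`, `"bml"`, `"vi"`, `"gibbs"`.
#' @param target_voxels mask size for the generator (default 5000).
#' @param L basis size for the spatial model; `NULL` selects it once per
#'   scenario via [choose_L()] on the first replicate.
#' @param kernel GP kernel (default Matern, length scale 0.3).
#' @param control list with optional `vi`, `gibbs`, `bml` engine options.
#' @param seed master seed.
#' @return Object of class `"bsir_simstudy"`: long data frame of
#'   per-scenario, per-method metric means and SDs, replicate counts and
#'   exclusions; raw per-replicate metrics in `attr(, "replicates")`.
#' @export
run_simulation_study <- function(scenarios = NULL, n_reps = 100L,
                                 methods = c("glm", "bml", "vi"),
                                 target_voxels = 5000L, L = NULL,
                                 kernel = matern_kernel(0.1),
                                 control = list(), seed = 1L) {
  if (is.null(scenarios))
    scenarios <- expand.grid(N = c(50L, 200L), sigma_eps = c(2, 5))
  methods <- match.arg(methods, c("glm", "bml", "vi", "gibbs"),
                       several.ok = TRUE)
  mask <- sim_mask(target_voxels, seed = seed)
  reps <- list()
  for (s in seq_len(nrow(scenarios))) {
    N <- scenarios$N[s]; s_eps <- scenarios$sigma_eps[s]
    snr <- scenarios$snr[s] %||% ifelse(s_eps == 2, 0.3, 0.05)
    truth <- sim_truth(mask, sigma_eps = s_eps, snr = snr,
                       kernel = kernel, seed = seed)
    basis <- NULL
    if (any(methods %in% c("vi", "gibbs"))) {
      Ls <- L
      if (is.null(Ls)) {
        d0 <- sim_dataset(truth, N = N, seed = seed + 1000L * s)
        Ls <- choose_L(d0$Y, cbind(1, d0$data$x), truth$domain, kernel,
                       Lmax = min(truth$domain$V, 500L),
                       control = list(rel_tol = 1e-6), seed = seed)$L
      }
      basis <- lowrank_basis(truth$domain, kernel, L = Ls, seed = seed)
    }
    for (r in seq_len(n_reps)) {
      rs <- seed + 1000L * s + r
      d <- sim_dataset(truth, N = N, seed = rs)
      for (m in methods) {
        res <- tryCatch(
          sim_fit_method(m, d, truth, L, basis, control, seed = rs),
          error = function(e) {
            warning(sprintf("scenario %d rep %d method %s failed: %s",
                            s, r, m, conditionMessage(e)))
            NULL
          })
        if (!is.null(res))
          reps[[length(reps) + 1L]] <- data.frame(
            scenario = s, N = N, sigma_eps = s_eps, rep = r, method = m,
            mse = res$mse, tpr = res$tpr, fdr = res$fdr,
            coverage = res$coverage)
      }
    }
  }
  repdf <- do.call(rbind, reps)
  agg <- stats::aggregate(
    cbind(mse, tpr, fdr, coverage) ~ scenario + N + sigma_eps + method,
    data = repdf, FUN = mean)
  sds <- stats::aggregate(
    cbind(mse, tpr, fdr, coverage) ~ scenario + N + sigma_eps + method,
    data = repdf, FUN = stats::sd)
  names(sds)[5:8] <- paste0(names(sds)[5:8], "_sd")
  out <- merge(agg, sds)
  out$n_reps <- as.integer(table(paste(repdf$scenario, repdf$method))[
    paste(out$scenario, out$method)])
  out <- out[order(out$scenario, out$method), ]
  rownames(out) <- NULL
  structure(out, replicates = repdf, class = c("bsir_simstudy", "data.frame"))
}

#' @export
print.bsir_simstudy <- function(x, digits = 3, ...) {
  cat("Simulation study (means over replicates; MSE, and TPR/FDR/coverage in %):\n")
  y <- data.frame(N = x$N, sigma_eps = x$sigma_eps, method = x$method,
                  mse = signif(x$mse, digits),
                  tpr = round(100 * x$tpr, 1), fdr = round(100 * x$fdr, 1),
                  coverage = round(100 * x$coverage, 1), n = x$n_reps)
  print(y, row.names = FALSE)
  invisible(x)
}
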
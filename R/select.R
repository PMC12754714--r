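# Selection of the basis size L: eigenvalue cumulative-variance screening
# followed by a leave-one-participant-out predictive grid search.

#' Candidate basis-size range from an eigenvalue spectrum
#'
#' Returns the smallest `L` whose leading eigenvalues explain at least
#' `lo` (and `hi`) of the total variance of an `Lmax`-point spectral
#' decomposition; the LOOCV grid search is restricted to this window.
#'
#' @param eigenvalues positive eigenvalues sorted nonincreasing.
#' @param lo,hi cumulative-variance fractions bounding the window
#'   (defaults 0.80 and 0.98).
#' @return Integer vector `c(L_lo, L_hi)`.
#' @examples
#' candidate_L_range(c(4, 3, 2, 1))  # cumulative 0.4, 0.7, 0.9, 1 -> c(3, 4)
#' @export
candidate_L_range <- function(eigenvalues, lo = 0.80, hi = 0.98) {
  if (length(eigenvalues) == 0L) stop("empty eigenvalue spectrum")
  if (any(eigenvalues <= 0)) stop("eigenvalues must be positive")
  if (is.unsorted(rev(eigenvalues))) stop("eigenvalues must be nonincreasing")
  cf <- cumsum(eigenvalues) / sum(eigenvalues)
  c(L_lo = which(cf >= lo)[1], L_hi = which(cf >= hi)[1])
}

# Posterior-mean fixed effects from either engine on a transformed dataset.
fit_engine_means <- function(td, g, engine, control) {
  if (engine == "vi") {
    vi <- run_cavi(td, config = control)
    list(alpha = vi$q$m_a, theta_beta = vi$q$M_b)
  } else {
    draws <- run_gibbs(td, g, utils::modifyList(
      list(n_chains = 1L, n_burn = 300L, n_keep = 300L), control))
    tb <- stack_draws(draws, "theta_beta")
    list(alpha = colMeans(stack_draws(draws, "alpha")),
         theta_beta = apply(tb, c(2, 3), mean))
  }
}

#' Leave-one-out predictive mean squared error for a basis
#'
#' For each participant in turn, fits the model on the remaining `N - 1`
#' participants (reusing the supplied basis, which depends only on the
#' coordinates) and predicts the held-out image from the fixed effects
#' (participant deviation set to zero).  Returns the grand mean over
#' participants and locations of the squared prediction error.
#'
#' @param Y `N` by `V` response matrix.
#' @param X `N` by `J+1` design matrix (intercept first).
#' @param basis a [lowrank_basis()].
#' @param engine `"vi"` (default, fast) or `"gibbs"`.
#' @param control engine options (see [bsir()]).
#' @return Scalar PMSE with attribute `"per_participant"`.  Folds on which
#'   the engine fails are skipped with a warning; more than 20% skipped is
#'   an error.
#' @export
loocv_pmse <- function(Y, X, basis, engine = c("vi", "gibbs"),
                       control = list()) {
  engine <- match.arg(engine)
  Y <- as.matrix(Y); X <- as.matrix(X)
  N <- nrow(Y)
  if (N < 3L) stop("need at least three participants for LOOCV")
  Yt <- project_responses(Y, basis)
  pmse <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    fold <- tryCatch({
      td <- list(Yt = Yt[-i, , drop = FALSE], X = X[-i, , drop = FALSE],
                 XtX = crossprod(X[-i, , drop = FALSE]),
                 h = basis$h, Phi_eta = basis$Phi_eta,
                 N = N - 1L, L = basis$L, L_eta = basis$L_eta,
                 J = ncol(X) - 1L)
      pm <- fit_engine_means(td, basis$g, engine, control)
      pred <- predict_images(pm$alpha, pm$theta_beta,
                             X[i, , drop = FALSE], basis)
      mean((Y[i, ] - pred)^2)
    }, error = function(e) {
      warning(sprintf("LOOCV fold %d failed (%s); skipped", i, conditionMessage(e)))
      NA_real_
    })
    pmse[i] <- fold
  }
  if (mean(is.na(pmse)) > 0.2) stop("more than 20% of LOOCV folds failed")
  out <- mean(pmse, na.rm = TRUE)
  attr(out, "per_participant") <- pmse
  out
}

#' Choose the number of basis functions by cumulative variance + LOOCV
#'
#' Computes an `Lmax`-point spectral decomposition, restricts candidates to
#' the window explaining 80--98% of its total variance, evaluates
#' `grid_size` evenly spaced candidates by leave-one-out predictive mean
#' squared error, and returns the candidate with the smallest PMSE (ties
#' resolved toward the smaller `L`).
#'
#' @param Y,X response matrix and design matrix (intercept first).
#' @param domain a [spatial_domain()].
#' @param kernel a [matern_kernel()].
#' @param Lmax upper bound for the decomposition; default
#'   `min(V, 2000)` (set by available computation).
#' @param grid_size number of candidates (default 5).
#' @param lo,hi cumulative-variance window (defaults 0.80, 0.98).
#' @param engine,control passed to [loocv_pmse()].
#' @param seed seed for inducing-point selection.
#' @return Object of class `"bsir_Lselect"`: selected `L`, candidate
#'   `grid`, per-candidate `pmse`, eigenvalue `spectrum`, `Lmax`.
#' @export
choose_L <- function(Y, X, domain, kernel, Lmax = NULL, grid_size = 5L,
                     lo = 0.80, hi = 0.98, engine = c("vi", "gibbs"),
                     control = list(), seed = 1L) {
  engine <- match.arg(engine)
  Lmax <- Lmax %||% min(domain$V, 2000L)
  if (Lmax > domain$V) stop("Lmax must not exceed V")
  ind <- select_inducing(domain, Lmax, seed = seed)
  dec <- nystrom_decompose(domain, kernel, ind)
  rng <- candidate_L_range(dec$lambda, lo, hi)
  grid <- unique(round(seq(rng[1], rng[2], length.out = grid_size)))
  pmse <- numeric(length(grid))
  for (k in seq_along(grid)) {
    b <- lowrank_basis(domain, kernel, L = grid[k], seed = seed)
    pmse[k] <- as.numeric(loocv_pmse(Y, X, b, engine = engine, control = control))
  }
  sel <- grid[which.min(pmse)]   # which.min takes the first (smaller L) on ties
  structure(list(L = sel, grid = grid, pmse = pmse,
                 window = rng, spectrum = dec$lambda, Lmax = Lmax,
                 engine = engine, seed = seed),
            class = "bsir_Lselect")
}

#' @export
print.bsir_Lselect <- function(x, ...) {
  cat(sprintf("Basis-size selection: L = %d (window %d..%d of Lmax = %d)\n",
              x$L, x$window[1], x$window[2], x$Lmax))
  print(data.frame(L = x$grid, pmse = signif(x$pmse, 6)), row.names = FALSE)
  invisible(x)
}
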
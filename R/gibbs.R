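# Conjugate Gibbs sampler for the reparameterized model.
#
# Parameter state: list(alpha ((J+1)-vector), theta_beta ((J+1) x L),
# theta_eta (N x L_eta), sig2 = c(alpha, beta, eta, eps),
# aux = c(alpha, beta, eta, eps), A).
# All full conditionals follow from conjugacy of the projected Gaussian
# likelihood with the normal / inverse-gamma hierarchy; the dense-algebra
# oracle tests in the suite are the authority for their correctness.

new_state <- function(alpha, theta_beta, theta_eta, sig2, aux, A = 100) {
  list(alpha = alpha, theta_beta = theta_beta, theta_eta = theta_eta,
       sig2 = sig2, aux = aux, A = A)
}

# alpha | . : precision (h'h/s2e) X'X + I/s2a, linear term X'(R1 h)/s2e
# where R1 = Yt - X theta_beta - theta_eta Phi_eta.
up_alpha <- function(state, td, draw = TRUE) {
  s2e <- state$sig2[["eps"]]; s2a <- state$sig2[["alpha"]]
  R1 <- td$Yt - td$X %*% state$theta_beta - state$theta_eta %*% td$Phi_eta
  hh <- sum(td$h^2)
  P <- (hh / s2e) * td$XtX + diag(1 / s2a, td$J + 1L)
  b <- crossprod(td$X, R1 %*% td$h) / s2e
  U <- chol(P)
  m <- chol_solve(U, b)
  if (!draw) return(list(mean = drop(m), prec = P))
  drop(m + backsolve(U, stats::rnorm(td$J + 1L)))
}

# theta_beta | . : per basis index l, precision X'X/s2e + I/s2b (shared),
# mean P^{-1} X' R2[,l] / s2e, with R2 = Yt - (X alpha) h' - theta_eta Phi_eta.
up_theta_beta <- function(state, td, draw = TRUE) {
  s2e <- state$sig2[["eps"]]; s2b <- state$sig2[["beta"]]
  R2 <- td$Yt - drop(td$X %*% state$alpha) %o% td$h -
    state$theta_eta %*% td$Phi_eta
  P <- td$XtX / s2e + diag(1 / s2b, td$J + 1L)
  U <- chol(P)
  M <- chol_solve(U, crossprod(td$X, R2) / s2e)
  if (!draw) return(list(mean = M, prec = P))
  M + backsolve(U, matrix(stats::rnorm((td$J + 1L) * td$L), td$J + 1L, td$L))
}

# theta_eta | . : per participant, precision Phi_eta Phi_eta'/s2e + I/s2h,
# mean P^{-1} Phi_eta r_i / s2e, with r_i the residual after fixed effects.
up_theta_eta <- function(state, td, draw = TRUE) {
  s2e <- state$sig2[["eps"]]; s2h <- state$sig2[["eta"]]
  R3 <- td$Yt - drop(td$X %*% state$alpha) %o% td$h - td$X %*% state$theta_beta
  P <- tcrossprod(td$Phi_eta) / s2e + diag(1 / s2h, td$L_eta)
  U <- chol(P)
  Tm <- R3 %*% t(td$Phi_eta) / s2e                  # N x L_eta
  M <- t(chol_solve(U, t(Tm)))
  if (!draw) return(list(mean = M, prec = P))
  M + t(backsolve(U, matrix(stats::rnorm(td$N * td$L_eta), td$L_eta, td$N)))
}

# Variances | . : conjugate inverse-gamma updates, one per block.
# shape = 1/2 + m/2 with m the number of governed coefficients,
# rate = 1/a + (sum of squared governed terms)/2.
up_variances <- function(state, td, draw = TRUE) {
  R <- td$Yt - mean_tilde(state, td)
  sh <- c(alpha = 0.5 + (td$J + 1L) / 2,
          beta  = 0.5 + (td$J + 1L) * td$L / 2,
          eta   = 0.5 + td$N * td$L_eta / 2,
          eps   = 0.5 + td$N * td$L / 2)
  ra <- c(alpha = 1 / state$aux[["alpha"]] + sum(state$alpha^2) / 2,
          beta  = 1 / state$aux[["beta"]]  + sum(state$theta_beta^2) / 2,
          eta   = 1 / state$aux[["eta"]]   + sum(state$theta_eta^2) / 2,
          eps   = 1 / state$aux[["eps"]]   + sum(R^2) / 2)
  if (!draw) return(list(shape = sh, rate = ra))
  pmax(rinvgamma(4, sh, ra), 1e-12)
}

# Auxiliaries | . : a ~ IG(1, 1/A^2 + 1/sigma^2) for each paired variance.
up_auxiliaries <- function(state, draw = TRUE) {
  ra <- 1 / state$A^2 + 1 / state$sig2
  if (!draw) return(list(shape = rep(1, 4), rate = ra))
  stats::setNames(rinvgamma(4, 1, ra), names(state$sig2))
}

# Identifiability recentering.  Both shifts leave the likelihood exactly
# invariant:
#  * participant means of theta_eta move into the intercept row of
#    theta_beta (sum_i eta_i(s_v) = 0);
#  * the voxel-mean of each reconstructed beta_j moves into alpha_j via
#    delta_j = (g' theta_beta_j)/(g' h), theta_beta_j -= delta_j h
#    (sum_v beta_j(s_v) = 0), with g = 1'Psi Lambda^{1/2}, h = 1'Phi.
recenter_state <- function(state, td, g) {
  cm <- colMeans(state$theta_eta)
  state$theta_eta <- sweep(state$theta_eta, 2, cm)
  state$theta_beta[1, ] <- state$theta_beta[1, ] + drop(cm %*% td$Phi_eta)
  gh <- sum(g * td$h)
  delta <- drop(state$theta_beta %*% g) / gh
  state$theta_beta <- state$theta_beta - delta %o% td$h
  state$alpha <- state$alpha + delta
  state
}

# Warm start shared by both engines.  alpha from least squares of the
# projected data onto (X alpha) h'; theta_beta from small-ridge solutions;
# theta_eta at zero; variances from residual moments.
init_state <- function(td, A = 100, scale = 1) {
  hh <- sum(td$h^2)
  alpha <- drop(solve(td$XtX, crossprod(td$X, td$Yt %*% td$h))) / hh
  R <- td$Yt - drop(td$X %*% alpha) %o% td$h
  theta_beta <- solve(td$XtX + diag(0.01, td$J + 1L), crossprod(td$X, R))
  R <- R - td$X %*% theta_beta
  s2e <- max(mean(R^2), 1e-6)
  sig2 <- c(alpha = max(mean(alpha^2), 0.1),
            beta  = max(mean(theta_beta^2), 0.1),
            eta   = max(0.5 * s2e, 0.01),
            eps   = s2e) * scale
  new_state(alpha, theta_beta,
            matrix(0, td$N, td$L_eta),
            sig2, aux = stats::setNames(rep(A^2, 4), names(sig2)), A = A)
}

#' Potential scale reduction factor (Gelman-Rubin diagnostic)
#'
#' Standard between/within-chain variance formula applied to scalar traces,
#' as used on the conditional log-likelihood to assess convergence.
#'
#' @param traces list of equal-length numeric vectors (one per chain).
#' @return The potential scale reduction factor; `Inf` (with a warning)
#'   when the within-chain variance is zero.
#' @export
gelman_rubin <- function(traces) {
  if (!is.list(traces) || length(traces) < 2L) stop("need at least two chains")
  n <- unique(lengths(traces))
  if (length(n) != 1L) stop("chains must have equal lengths")
  if (n < 10L) stop("chains too short for the diagnostic")
  m <- length(traces)
  means <- vapply(traces, mean, 0)
  W <- mean(vapply(traces, stats::var, 0))
  B <- n * stats::var(means)
  if (W == 0) {
    warning("zero within-chain variance; R-hat undefined")
    return(Inf)
  }
  # values below 1 are finite-sample artifacts; report 1 as the floor
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

# Run the Gibbs sampler.  Update cycle per iteration:
# alpha -> theta_beta -> theta_eta -> variances -> auxiliaries -> recenter.
# Deterministic given config$seed.  Returns a "bsir_draws" object.
run_gibbs <- function(td, g, config = list()) {
  n_chains <- config$n_chains %||% 3L
  n_burn <- config$n_burn %||% 4000L
  n_keep <- config$n_keep %||% 1000L
  thin <- config$thin %||% 1L
  seed <- config$seed %||% 1L
  A <- config$A %||% 100
  store_eta <- config$store_eta %||% TRUE
  if (n_keep < 1L) stop("n_keep must be positive")
  J1 <- td$J + 1L
  chains <- vector("list", n_chains)
  overdisp <- c(0.5, 1, 2)
  for (ch in seq_len(n_chains)) {
    set.seed(as.integer(seed + 1000L * (ch - 1L)))
    state <- init_state(td, A = A, scale = overdisp[(ch - 1L) %% 3L + 1L])
    alpha_d <- matrix(NA_real_, n_keep, J1)
    tb_d <- array(NA_real_, c(n_keep, J1, td$L))
    te_d <- if (store_eta) array(NA_real_, c(n_keep, td$N, td$L_eta)) else NULL
    sig2_d <- matrix(NA_real_, n_keep, 4,
                     dimnames = list(NULL, names(state$sig2)))
    ll <- numeric(n_keep)
    kept <- 0L
    n_iter <- n_burn + n_keep * thin
    for (it in seq_len(n_iter)) {
      state$alpha <- up_alpha(state, td)
      state$theta_beta <- up_theta_beta(state, td)
      state$theta_eta <- up_theta_eta(state, td)
      s2 <- up_variances(state, td)
      state$sig2 <- stats::setNames(s2, names(state$sig2))
      state$aux <- up_auxiliaries(state)
      state <- recenter_state(state, td, g)
      if (it > n_burn && (it - n_burn) %% thin == 0L) {
        kept <- kept + 1L
        alpha_d[kept, ] <- state$alpha
        tb_d[kept, , ] <- state$theta_beta
        if (store_eta) te_d[kept, , ] <- state$theta_eta
        sig2_d[kept, ] <- state$sig2
        ll[kept] <- conditional_loglik(state, td)
      }
    }
    chains[[ch]] <- list(alpha = alpha_d, theta_beta = tb_d,
                         theta_eta = te_d, sig2 = sig2_d, loglik = ll)
  }
  rhat <- if (n_chains >= 2L && n_keep >= 10L)
    gelman_rubin(lapply(chains, `[[`, "loglik")) else NA_real_
  structure(list(chains = chains, n_chains = n_chains, n_burn = n_burn,
                 n_keep = n_keep, thin = thin, seed = seed, rhat = rhat),
            class = "bsir_draws")
}

# Stack a per-chain component into one (n_chains*n_keep) x ... array.
stack_draws <- function(draws, what) {
  parts <- lapply(draws$chains, `[[`, what)
  if (is.null(parts[[1]])) return(NULL)
  if (is.matrix(parts[[1]])) return(do.call(rbind, parts))
  out <- parts[[1]]
  if (length(parts) > 1L)
    for (k in 2:length(parts)) out <- abind3(out, parts[[k]])
  out
}

# Minimal 3-D array bind along the first margin.
abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(length(da) == 3L, all(da[-1] == db[-1]))
  out <- array(NA_real_, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}
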
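# Model core shared by both inference engines: assembly of the transformed
# dataset, subspace projection, effect reconstruction, likelihood.

# Internal container for the reparameterized regression problem.
# Yt = Y Phi (N x L), X = design (N x (J+1), first column all ones),
# h = 1_V^T Phi, Phi_eta (L_eta x L).
make_tdata <- function(Y, X, basis) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (ncol(Y) != nrow(basis$Phi)) stop("Y and basis disagree on V")
  if (nrow(Y) != nrow(X)) stop("Y and X disagree on N")
  if (anyNA(Y) || anyNA(X)) stop("missing values are not supported; remove or reject them upstream")
  if (any(X[, 1] != 1)) stop("first design column must be the intercept (all ones)")
  list(Yt = Y %*% basis$Phi, X = X, XtX = crossprod(X),
       h = basis$h, Phi_eta = basis$Phi_eta,
       N = nrow(Y), L = basis$L, L_eta = basis$L_eta, J = ncol(X) - 1L)
}

#' Project response images onto the low-rank basis
#'
#' Computes the transformed responses \eqn{\tilde y_i = y_i^\top \Phi},
#' reducing each length-`V` image to `L` basis-projected outcomes.
#'
#' @param Y `N` by `V` response matrix.
#' @param basis a [lowrank_basis()].
#' @return `N` by `L` matrix.
#' @export
project_responses <- function(Y, basis) {
  stopifnot(inherits(basis, "bsir_basis"))
  Y <- as.matrix(Y)
  if (ncol(Y) != nrow(basis$Phi)) stop("Y and basis disagree on V")
  Y %*% basis$Phi
}

#' Reconstruct a voxel-level effect map from basis coefficients
#'
#' Returns \eqn{\alpha_j 1_V + \Psi \Lambda^{1/2} \theta_{\beta j}}, the
#' voxel-level effect of covariate `j` implied by a global effect and its
#' basis coefficients.
#'
#' @param alpha_j scalar global effect.
#' @param theta_j length-`L` coefficient vector.
#' @param basis a [lowrank_basis()].
#' @return Length-`V` numeric vector.
#' @export
reconstruct_effect <- function(alpha_j, theta_j, basis) {
  stopifnot(inherits(basis, "bsir_basis"))
  if (length(theta_j) != basis$L) stop("theta_j has wrong length")
  drop(alpha_j + basis$B %*% theta_j)
}

# Mean of the transformed responses under a parameter state:
# M_i = (x_i^T alpha) h + x_i^T theta_beta + theta_eta_i^T Phi_eta.
mean_tilde <- function(state, td) {
  drop(td$X %*% state$alpha) %o% td$h +
    td$X %*% state$theta_beta +
    state$theta_eta %*% td$Phi_eta
}

# Conditional log-likelihood of the projected data given a state:
# sum_i log N(ytilde_i | M_i, sigma2_eps I_L).
conditional_loglik <- function(state, td) {
  s2e <- state$sig2[["eps"]]
  if (s2e <= 0) stop("sigma2_eps must be positive")
  R <- td$Yt - mean_tilde(state, td)
  -0.5 * td$N * td$L * log(2 * pi * s2e) - 0.5 * sum(R^2) / s2e
}

# Predicted images for design rows X_new (fixed effects only unless
# include_eta, in which case theta_eta rows are added for in-sample rows).
predict_images <- function(alpha, theta_beta, X_new, basis,
                           theta_eta = NULL) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(alpha)) stop("X_new has wrong number of columns")
  out <- drop(X_new %*% alpha) %o% rep(1, nrow(basis$B)) +
    (X_new %*% theta_beta) %*% t(basis$B)
  if (!is.null(theta_eta)) out <- out + theta_eta %*% t(basis$B_eta)
  out
}
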
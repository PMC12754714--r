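# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

cache <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

# small regular grid domain (V = n^2)
grid_domain <- function(n = 10) {
  spatial_domain(as.matrix(expand.grid(x = seq_len(n), y = seq_len(n))))
}

# identity-basis transformed toy problem: V = L, Psi = I, Lambda = I.
# Full conditionals then coincide with dense Bayesian linear-model algebra.
identity_td <- function(Y, X, L_eta = ncol(Y)) {
  V <- ncol(Y)
  basis <- structure(list(
    domain = list(V = V), kernel = matern_kernel(0.3),
    L = V, L_eta = L_eta, inducing = seq_len(V), inducing_eta = seq_len(L_eta),
    Psi = diag(V), lambda = rep(1, V),
    Psi_eta = diag(V)[, seq_len(L_eta), drop = FALSE],
    lambda_eta = rep(1, L_eta),
    Phi = diag(V), B = diag(V),
    B_eta = diag(V)[, seq_len(L_eta), drop = FALSE],
    Phi_eta = t(diag(V)[, seq_len(L_eta), drop = FALSE]),
    h = rep(1, V), g = rep(1, V)), class = "bsir_basis")
  list(td = make_tdata(Y, X, basis), basis = basis)
}

# mid-sized simulated fixture shared across engine tests
fixture_sim <- function() cache("sim", {
  mask <- sim_mask(400, seed = 42)
  truth <- sim_truth(mask, sigma_eps = 2, snr = 0.3, seed = 42)
  d <- sim_dataset(truth, N = 40, seed = 7)
  basis <- lowrank_basis(mask, truth$kernel, L = 60, seed = 1)
  list(mask = mask, truth = truth, d = d, basis = basis)
})

# state filled with fixed small values, for update-oracle tests
fixed_state <- function(td, s2 = c(alpha = 1, beta = 1, eta = 1, eps = 1),
                        A = 100) {
  bsir:::new_state(
    alpha = rep(0, td$J + 1L),
    theta_beta = matrix(0, td$J + 1L, td$L),
    theta_eta = matrix(0, td$N, td$L_eta),
    sig2 = s2, aux = stats::setNames(rep(A^2, 4), names(s2)), A = A)
}

make_tdata <- bsir:::make_tdata
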
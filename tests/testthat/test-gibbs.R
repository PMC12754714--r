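# Full-conditional correctness (dense oracles), sampling behavior,
# identifiability, diagnostics.

test_that("alpha full conditional matches scalar conjugate algebra", {
  # J=0, N=1, L=1, identity basis, residual 2, unit variances:
  # precision = 1 + 1 = 2, mean = residual/2 = 1
  id <- identity_td(matrix(2, 1, 1), matrix(1, 1, 1), L_eta = 1)
  st <- fixed_state(id$td)
  res <- bsir:::up_alpha(st, id$td, draw = FALSE)
  expect_equal(res$mean, 1)
  expect_equal(1 / res$prec[1, 1], 0.5)
  # prior domination
  st$sig2[["alpha"]] <- 1e-8
  set.seed(1)
  expect_lt(abs(bsir:::up_alpha(st, id$td)), 1e-3)
})

test_that("full-conditional moments match a dense Bayesian linear-model oracle", {
  # V = L identity basis, small dims; compare against posterior moments of
  # the explicit vectorized regression computed by generic ridge algebra
  set.seed(21)
  N <- 4; V <- 3; Le <- 2
  Y <- matrix(stats::rnorm(N * V), N)
  X <- cbind(1, stats::rnorm(N))
  id <- identity_td(Y, X, L_eta = Le)
  td <- id$td
  st <- fixed_state(td, s2 = c(alpha = 0.8, beta = 1.3, eta = 0.6, eps = 0.5))
  st$alpha <- c(0.3, -0.2)
  st$theta_beta <- matrix(stats::rnorm(2 * V), 2)
  st$theta_eta <- matrix(stats::rnorm(N * Le), N)

  dense_post <- function(Z, y, s2e, s2p) {
    P <- crossprod(Z) / s2e + diag(1 / s2p, ncol(Z))
    list(mean = drop(solve(P, crossprod(Z, y))) / s2e, prec = P)
  }
  # alpha: responses vec(R1) stacked by basis column l, design rows x_i h_l
  R1 <- td$Yt - X %*% st$theta_beta - st$theta_eta %*% td$Phi_eta
  o <- dense_post(kronecker(rep(1, V), X) * rep(td$h, each = N),
                  as.vector(R1), 0.5, 0.8)
  a <- bsir:::up_alpha(st, td, draw = FALSE)
  expect_equal(a$mean, o$mean, tolerance = 1e-8)
  expect_equal(unname(a$prec), unname(o$prec), tolerance = 1e-8)

  # theta_beta, column l: ridge of R2[, l] on X
  R2 <- td$Yt - drop(X %*% st$alpha) %o% td$h - st$theta_eta %*% td$Phi_eta
  tb <- bsir:::up_theta_beta(st, td, draw = FALSE)
  for (l in seq_len(V)) {
    o <- dense_post(X, R2[, l], 0.5, 1.3)
    expect_equal(tb$mean[, l], o$mean, tolerance = 1e-8)
    expect_equal(unname(tb$prec), unname(o$prec), tolerance = 1e-8)
  }
  # theta_eta, participant i: ridge of R3[i, ] on t(Phi_eta)
  R3 <- td$Yt - drop(X %*% st$alpha) %o% td$h - X %*% st$theta_beta
  te <- bsir:::up_theta_eta(st, td, draw = FALSE)
  for (i in seq_len(N)) {
    o <- dense_post(t(td$Phi_eta), R3[i, ], 0.5, 0.6)
    expect_equal(te$mean[i, ], o$mean, tolerance = 1e-8)
    expect_equal(unname(te$prec), unname(o$prec), tolerance = 1e-8)
  }
})

test_that("theta_eta conditional simplifies with orthonormal rows", {
  # Phi_eta with orthonormal rows, unit variances: precision 2 I,
  # conditional mean (Phi_eta residual)/2
  set.seed(3)
  N <- 3; V <- 4; Le <- 2
  Y <- matrix(stats::rnorm(N * V), N)
  id <- identity_td(Y, matrix(1, N, 1), L_eta = Le)
  td <- id$td   # Phi_eta rows are unit vectors: orthonormal
  st <- fixed_state(td)
  te <- bsir:::up_theta_eta(st, td, draw = FALSE)
  expect_equal(unname(te$prec), diag(2, Le))
  R3 <- td$Yt - drop(td$X %*% st$alpha) %o% td$h - td$X %*% st$theta_beta
  expect_equal(te$mean, R3 %*% t(td$Phi_eta) / 2, tolerance = 1e-10)
})

test_that("sampled conditional moments match analytics within Monte Carlo error", {
  id <- identity_td(matrix(2, 1, 1), matrix(1, 1, 1), L_eta = 1)
  st <- fixed_state(id$td)
  set.seed(5)
  draws <- replicate(10000, bsir:::up_alpha(st, id$td))
  se_mean <- sqrt(0.5 / 10000)
  expect_lt(abs(mean(draws) - 1), 3 * se_mean)
  se_var <- 0.5 * sqrt(2 / 9999)
  expect_lt(abs(stats::var(draws) - 0.5), 3 * se_var)
})

test_that("variance conditionals have the conjugate shapes and rates", {
  set.seed(6)
  id <- identity_td(matrix(stats::rnorm(4), 2, 2), matrix(1, 2, 1), L_eta = 1)
  td <- id$td
  st <- fixed_state(td)
  st$alpha <- 2            # J = 0
  st$aux[] <- 1
  v <- bsir:::up_variances(st, td, draw = FALSE)
  expect_equal(unname(v$shape[["alpha"]]), 1)       # 1/2 + 1/2
  expect_equal(unname(v$rate[["alpha"]]), 1 + 4 / 2)  # 1/a + alpha^2/2 = 3
  # zero coefficients: rate reduces to 1/a
  st$theta_beta[] <- 0
  v <- bsir:::up_variances(st, td, draw = FALSE)
  expect_equal(unname(v$rate[["beta"]]), 1)
  expect_equal(unname(v$shape[["beta"]]), 0.5 + td$L / 2)
})

test_that("auxiliary conditionals close the half-Cauchy mixture", {
  td <- identity_td(matrix(0, 1, 1), matrix(1, 1, 1), L_eta = 1)$td
  st <- fixed_state(td)
  st$A <- 100
  st$sig2[] <- 1
  a <- bsir:::up_auxiliaries(st, draw = FALSE)
  expect_equal(unname(a$shape), rep(1, 4))
  expect_equal(unname(a$rate[["alpha"]]), 1 / 100^2 + 1)
  st$sig2[] <- 1e12
  expect_equal(unname(bsir:::up_auxiliaries(st, draw = FALSE)$rate[["eps"]]),
               1e-4, tolerance = 1e-6)
  # composing a ~ IG(1/2, 1/A^2), sigma^2 | a ~ IG(1/2, 1/a) yields a
  # half-Cauchy(A) marginal for sigma
  set.seed(7)
  A <- 1
  a_d <- bsir:::rinvgamma(1e5, 0.5, 1 / A^2)
  sig <- sqrt(bsir:::rinvgamma(1e5, 0.5, 1 / a_d))
  ks <- suppressWarnings(stats::ks.test(sig, function(q) 2 / pi * atan(q / A)))
  expect_gt(ks$p.value, 0.01)
})

test_that("successive-conditional (Geweke) sampling preserves the prior", {
  # iterate (parameters | data) Gibbs blocks and (data | parameters) draws;
  # the parameter marginals must stay at the prior.  Recentering is an
  # identifiability convention, not part of the prior, so the raw blocks
  # are tested.
  set.seed(8)
  N <- 2; V <- 2; Le <- 1; A <- 1
  X <- matrix(1, N, 1)
  id <- identity_td(matrix(0, N, V), X, L_eta = Le)
  td <- id$td
  st <- fixed_state(td, s2 = c(alpha = 1, beta = 1, eta = 1, eps = 1), A = A)
  st$aux[] <- 1
  n_iter <- 6000L
  keep <- matrix(NA_real_, n_iter, 2)
  for (it in seq_len(n_iter)) {
    td$Yt <- bsir:::mean_tilde(st, td) +
      sqrt(st$sig2[["eps"]]) * matrix(stats::rnorm(N * V), N)
    st$alpha <- bsir:::up_alpha(st, td)
    st$theta_beta <- bsir:::up_theta_beta(st, td)
    st$theta_eta <- bsir:::up_theta_eta(st, td)
    st$sig2 <- stats::setNames(bsir:::up_variances(st, td), names(st$sig2))
    st$aux <- bsir:::up_auxiliaries(st)
    keep[it, ] <- c(st$sig2[["beta"]], st$sig2[["eps"]])
  }
  thin <- keep[seq(1000, n_iter, by = 10), ]
  fwd <- sqrt(bsir:::rinvgamma(5000, 0.5, 1 / bsir:::rinvgamma(5000, 0.5, 1)))
  for (j in 1:2) {
    ks <- suppressWarnings(stats::ks.test(sqrt(thin[, j]), fwd))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("recentering zeroes the constraints and leaves the likelihood invariant", {
  set.seed(9)
  fx <- fixture_sim()
  td <- make_tdata(fx$d$Y, cbind(1, fx$d$data$x), fx$basis)
  st <- bsir:::init_state(td)
  st$theta_eta <- matrix(stats::rnorm(td$N * td$L_eta), td$N)
  st$theta_beta <- st$theta_beta + 0.5
  ll0 <- bsir:::conditional_loglik(st, td)
  st2 <- bsir:::recenter_state(st, td, fx$basis$g)
  expect_equal(bsir:::conditional_loglik(st2, td), ll0, tolerance = 1e-9)
  expect_lt(max(abs(colSums(st2$theta_eta))), 1e-10)
  for (j in 1:2) {
    beta_j <- reconstruct_effect(0, st2$theta_beta[j, ], fx$basis)
    expect_lt(abs(mean(beta_j)), 1e-8)
  }
})

test_that("the sampler is deterministic given seeds and keeps constraints", {
  fx <- fixture_sim()
  td <- make_tdata(fx$d$Y, cbind(1, fx$d$data$x), fx$basis)
  cfg <- list(n_chains = 2L, n_burn = 30L, n_keep = 30L, seed = 11L)
  d1 <- bsir:::run_gibbs(td, fx$basis$g, cfg)
  d2 <- bsir:::run_gibbs(td, fx$basis$g, cfg)
  expect_identical(d1$chains[[1]]$alpha, d2$chains[[1]]$alpha)
  expect_identical(d1$chains[[2]]$sig2, d2$chains[[2]]$sig2)
  # constraints hold for every kept draw
  te <- d1$chains[[1]]$theta_eta
  expect_lt(max(abs(apply(te, c(1, 3), sum))), 1e-9)
  tb <- d1$chains[[1]]$theta_beta
  for (k in c(1, 30)) {
    bmap <- reconstruct_effect(0, tb[k, 2, ], fx$basis)
    expect_lt(abs(mean(bmap)), 1e-7)
  }
})

test_that("posterior recovers strong synthetic signal within 2 SD at 90% of voxels", {
  fx <- fixture_sim()
  d <- sim_dataset(fx$truth, N = 50, seed = 23)
  fit <- bsir(~ x, data = d$data, images = d$Y, basis = fx$basis,
              engine = "gibbs", standardize = FALSE, seed = 2,
              control = list(n_chains = 2L, n_burn = 200L, n_keep = 200L))
  s <- summary(fit)
  V <- fx$mask$V
  ok <- sapply(1:2, function(j)
    mean(abs(s$effects[[j]]$mean - fx$truth$beta[, j]) <=
           2 * s$effects[[j]]$sd))
  expect_gt(mean(ok), 0.90)
})

test_that("posterior SD of voxel effects contracts as N doubles", {
  fx <- fixture_sim()
  sds <- sapply(c(40, 80), function(N) {
    d <- sim_dataset(fx$truth, N = N, seed = 31)
    fit <- bsir(~ x, data = d$data, images = d$Y, basis = fx$basis,
                engine = "gibbs", standardize = FALSE, seed = 3,
                control = list(n_chains = 1L, n_burn = 120L, n_keep = 120L,
                               store_eta = FALSE))
    stats::median(summary(fit)$effects[[2]]$sd)
  })
  expect_lt(sds[2], sds[1])
})

test_that("Gelman-Rubin diagnostic behaves across regimes", {
  set.seed(12)
  tr <- stats::rnorm(1000)
  expect_equal(gelman_rubin(list(tr, tr)), 1.0, tolerance = 1e-12)
  two <- list(stats::rnorm(1000), stats::rnorm(1000))
  expect_lt(gelman_rubin(two), 1.1)
  apart <- list(stats::rnorm(1000), stats::rnorm(1000, mean = 10))
  expect_gt(gelman_rubin(apart), 3)
  expect_warning(rh <- gelman_rubin(list(rep(1, 20), rep(1, 20))), "zero")
  expect_identical(rh, Inf)
  expect_error(gelman_rubin(list(1:20)), "two chains")
  expect_error(gelman_rubin(list(1:5, 1:5)), "short")
})

test_that("per-iteration cost grows about linearly in N", {
  fx <- fixture_sim()
  tm <- sapply(c(40, 160), function(N) {
    d <- sim_dataset(fx$truth, N = N, seed = 41)
    td <- make_tdata(d$Y, cbind(1, d$data$x), fx$basis)
    st <- bsir:::init_state(td)
    set.seed(1)
    system.time(for (i in 1:60) {
      st$alpha <- bsir:::up_alpha(st, td)
      st$theta_beta <- bsir:::up_theta_beta(st, td)
      st$theta_eta <- bsir:::up_theta_eta(st, td)
      st$sig2 <- stats::setNames(bsir:::up_variances(st, td), names(st$sig2))
      st$aux <- bsir:::up_auxiliaries(st)
    })[["elapsed"]]
  })
  # N grows 4x; allow [1, 8] for the time ratio (linear with factor-2 slack,
  # and a floor for fixed overheads)
  expect_lt(tm[2] / max(tm[1], 1e-3), 8)
})
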
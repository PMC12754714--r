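# Mean-field CAVI: fixed points, exactness in single-block toys, ELBO
# monotonicity and evidence identity, agreement with the Gibbs engine.

# toy with only theta_beta unknown: J=0, identity basis, known variances
single_block_toy <- function(N = 4, V = 3, s2e = 0.5, s2b = 2) {
  set.seed(17)
  Y <- matrix(stats::rnorm(N * V), N)
  id <- identity_td(Y, matrix(1, N, 1), L_eta = 1)
  td <- id$td
  free <- "theta_beta"
  q <- bsir:::init_q(td, free = free,
                     state = fixed_state(td, s2 = c(alpha = 1, beta = s2b,
                                                    eta = 1, eps = s2e)))
  q$m_a <- 0; q$M_e[] <- 0
  list(td = td, q = q, Y = Y, s2e = s2e, s2b = s2b, N = N, V = V)
}

test_that("CAVI factor equals the exact conditional in the single-block limit", {
  toy <- single_block_toy()
  q1 <- bsir:::cavi_step(toy$q, toy$td)
  # exact posterior per basis column l: N(mean, v) with
  # v = (N/s2e + 1/s2b)^-1, mean = v * sum_i y_il / s2e
  v <- 1 / (toy$N / toy$s2e + 1 / toy$s2b)
  expect_equal(q1$S_b[1, 1], v, tolerance = 1e-10)
  expect_equal(drop(q1$M_b), v * colSums(toy$td$Yt) / toy$s2e,
               tolerance = 1e-10)
  # fixed point: a second sweep leaves the factor unchanged
  q2 <- bsir:::cavi_step(q1, toy$td)
  expect_equal(q2$M_b, q1$M_b, tolerance = 1e-10)
  expect_equal(q2$S_b, q1$S_b, tolerance = 1e-10)
})

test_that("converged single-block ELBO equals the exact log marginal likelihood", {
  toy <- single_block_toy()
  vi <- bsir:::run_cavi(toy$td, config = list(rel_tol = 1e-12), free = "theta_beta",
                        q0 = toy$q)
  # evidence: independent across columns, y_.l ~ N(0, s2b J + s2e I)
  Sigma <- toy$s2b * matrix(1, toy$N, toy$N) + diag(toy$s2e, toy$N)
  logml <- sum(apply(toy$td$Yt, 2, function(y)
    mvn_logpdf <- -0.5 * (toy$N * log(2 * pi) +
                          determinant(Sigma)$modulus +
                          drop(y %*% solve(Sigma, y)))))
  expect_equal(vi$elbo, logml, tolerance = 1e-6)
})

test_that("prior-only toy: zero data gives the analytic prior-limit ELBO", {
  toy <- single_block_toy()
  toy$td$Yt[] <- 0
  vi <- bsir:::run_cavi(toy$td, config = list(rel_tol = 1e-12),
                        free = "theta_beta", q0 = toy$q)
  # evidence with y = 0: product of N(0 | 0, Sigma) densities
  Sigma <- toy$s2b * matrix(1, toy$N, toy$N) + diag(toy$s2e, toy$N)
  logml <- -0.5 * toy$V * (toy$N * log(2 * pi) + determinant(Sigma)$modulus)
  expect_equal(vi$elbo, as.numeric(logml), tolerance = 1e-6)
})

test_that("mean-field variances underestimate correlated-posterior marginals", {
  # two-block toy: alpha and theta_beta both unknown with strongly
  # correlated posterior; dense 2x2 Gaussian oracle per column
  set.seed(18)
  N <- 3; V <- 1
  Y <- matrix(stats::rnorm(N), N, V)
  id <- identity_td(Y, matrix(1, N, 1), L_eta = 1)
  td <- id$td
  s2e <- 1; s2a <- 4; s2b <- 4
  q <- bsir:::init_q(td, free = c("alpha", "theta_beta"),
                     state = fixed_state(td, s2 = c(alpha = s2a, beta = s2b,
                                                    eta = 1, eps = s2e)))
  q$M_e[] <- 0
  for (i in 1:200) q <- bsir:::cavi_step(q, td)
  # joint posterior of (alpha, theta_b): design [h X | X] = [1 1] per obs
  Z <- cbind(1, 1)[rep(1, N), ]
  P <- crossprod(Z) / s2e + diag(c(1 / s2a, 1 / s2b))
  Cov <- solve(P)
  expect_lt(q$S_a[1, 1], Cov[1, 1])
  expect_lt(q$S_b[1, 1], Cov[2, 2])
})

test_that("the ELBO is nondecreasing on real fits and the trace is reproducible", {
  fx <- fixture_sim()
  fit <- bsir(~ x, data = fx$d$data, images = fx$d$Y, basis = fx$basis,
              engine = "vi", standardize = FALSE, seed = 5)
  expect_true(all(diff(fit$vi$elbo_trace) >= -1e-8))
  expect_true(fit$vi$converged)
  fit2 <- bsir(~ x, data = fx$d$data, images = fx$d$Y, basis = fx$basis,
               engine = "vi", standardize = FALSE, seed = 5)
  expect_identical(fit$vi$elbo_trace, fit2$vi$elbo_trace)
})

test_that("CAVI converges quickly on the simulation fixture", {
  fx <- fixture_sim()
  vi <- bsir:::run_cavi(make_tdata(fx$d$Y, cbind(1, fx$d$data$x), fx$basis),
                        config = list(rel_tol = 1e-6))
  expect_true(vi$converged)
  expect_lte(vi$iterations, 200)
})

test_that("VI and Gibbs posterior mean effect maps agree (r > 0.99)", {
  fx <- fixture_sim()
  common <- list(data = fx$d$data, images = fx$d$Y, basis = fx$basis)
  fv <- bsir(~ x, data = common$data, images = common$images,
             basis = common$basis, engine = "vi", standardize = FALSE, seed = 1)
  fg <- bsir(~ x, data = common$data, images = common$images,
             basis = common$basis, engine = "gibbs", standardize = FALSE,
             seed = 1, control = list(n_chains = 3L, n_burn = 300L,
                                      n_keep = 500L, store_eta = FALSE))
  expect_gt(stats::cor(as.vector(coef(fv)), as.vector(coef(fg))), 0.99)
  # median voxelwise |VI - Gibbs| below 0.1 posterior SD
  sv <- summary(fv); sg <- summary(fg)
  for (j in 1:2) {
    dd <- abs(sv$effects[[j]]$mean - sg$effects[[j]]$mean)
    expect_lt(stats::median(dd / sg$effects[[j]]$sd), 0.1)
  }
})

test_that("a broken update is caught by the monotonicity guard", {
  toy <- single_block_toy()
  q <- bsir:::cavi_step(toy$q, toy$td)
  q$M_b <- q$M_b + 50      # corrupt the state: ELBO must drop
  expect_lt(bsir:::compute_elbo(q, toy$td),
            bsir:::compute_elbo(bsir:::cavi_step(toy$q, toy$td), toy$td))
})
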
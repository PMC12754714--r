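# Effect summaries, evidence measures, activation thresholds, PPC.

test_that("Gaussian VI marginals give textbook P+ and Es values", {
  fx <- fixture_sim()
  fit <- bsir(~ x, data = fx$d$data, images = fx$d$Y, basis = fx$basis,
              engine = "vi", standardize = FALSE, seed = 1)
  # forge a factor with mean exactly 1.96 sd at one location to pin the
  # normal-CDF arithmetic: P+ = 0.975, Es = 0.95
  q <- fit$vi$q
  b2 <- rowSums(fx$basis$B^2)
  sdv <- sqrt(q$S_a[1, 1] + q$S_b[1, 1] * b2[1])
  q$m_a[1] <- 1.96 * sdv
  q$M_b[1, ] <- 0
  fit$vi$q <- q
  s <- summary(fit)
  expect_equal(s$effects[[1]]$p_plus[1], stats::pnorm(1.96), tolerance = 1e-6)
  expect_equal(s$effects[[1]]$es[1], 2 * (stats::pnorm(1.96) - 0.5),
               tolerance = 1e-6)
  # intervals bracket the mean; Es = 2 (P+ - 1/2) everywhere
  e <- s$effects[[2]]
  expect_true(all(e$lower <= e$mean & e$mean <= e$upper))
  expect_equal(e$es, 2 * (e$p_plus - 0.5))
  expect_true(all(e$p_plus >= 0 & e$p_plus <= 1))
})

test_that("draw-based summaries handle degenerate and symmetric cases", {
  fx <- fixture_sim()
  fit <- bsir(~ x, data = fx$d$data, images = fx$d$Y, basis = fx$basis,
              engine = "gibbs", standardize = FALSE, seed = 1,
              control = list(n_chains = 1L, n_burn = 50L, n_keep = 60L,
                             store_eta = FALSE))
  # identical draws with positive effect: P+ = 1, Es = 1, zero-width intervals
  ch <- fit$draws$chains[[1]]
  ch$alpha[, 1] <- 1
  ch$theta_beta[, 1, ] <- 0
  fit$draws$chains[[1]] <- ch
  s <- summary(fit)
  expect_true(all(s$effects[[1]]$p_plus == 1))
  expect_true(all(s$effects[[1]]$es == 1))
  expect_equal(s$effects[[1]]$upper - s$effects[[1]]$lower, rep(0, fx$mask$V))
  # draws symmetric around zero: P+ ~ 0.5, Es ~ 0
  ch$alpha[, 1] <- rep(c(-1, 1), 30)
  ch$theta_beta[, 1, ] <- 0
  fit$draws$chains[[1]] <- ch
  s <- summary(fit)
  expect_true(all(abs(s$effects[[1]]$es) < 0.05))
  # too few draws is an error
  fit$draws$chains[[1]] <- lapply(ch, function(a)
    if (is.matrix(a)) a[1:10, , drop = FALSE]
    else if (length(dim(a)) == 3) a[1:10, , , drop = FALSE] else a[1:10])
  fit$draws$n_keep <- 10L
  expect_error(summary(fit), "too few")
})

test_that("Es maps flip sign under response negation", {
  fx <- fixture_sim()
  f1 <- bsir(~ x, data = fx$d$data, images = fx$d$Y, basis = fx$basis,
             engine = "vi", standardize = FALSE, seed = 1)
  f2 <- bsir(~ x, data = fx$d$data, images = -fx$d$Y, basis = fx$basis,
             engine = "vi", standardize = FALSE, seed = 1)
  s1 <- summary(f1); s2 <- summary(f2)
  for (j in 1:2) {
    expect_equal(s2$effects[[j]]$mean, -s1$effects[[j]]$mean, tolerance = 1e-6)
    expect_equal(s2$effects[[j]]$es, -s1$effects[[j]]$es, tolerance = 1e-6)
  }
})

test_that("evidence conversion from p-values follows the signed 1-p rule", {
  expect_equal(evidence_from_pvalue(0.04, +1), 0.96)
  expect_equal(evidence_from_pvalue(1, -1), 0)
  expect_equal(evidence_from_pvalue(0.05, -1), -0.95)
  expect_equal(evidence_from_pvalue(c(0.1, 0.2), c(1, -1)), c(0.9, -0.8))
  expect_error(evidence_from_pvalue(1.2, 1), "\\[0, 1\\]")
})

test_that("activation thresholding is exact at the boundary and monotone", {
  es <- c(0, 0.951, -0.97, 0.95, 0.4)
  expect_identical(threshold_active(rep(0, 5)), rep(FALSE, 5))
  expect_identical(threshold_active(es), c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(threshold_active(es, mode = "positive"),
                   c(FALSE, TRUE, FALSE, FALSE, FALSE))
  set.seed(1)
  es <- stats::runif(200, -1, 1)
  sizes <- sapply(seq(0.5, 0.99, by = 0.07), function(th)
    sum(threshold_active(es, th)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("posterior predictive replicates bracket the observed density", {
  # well-specified check: participant deviations disabled in the generator
  # so the fitted model matches the data-generating process
  fx <- fixture_sim()
  d <- sim_dataset(fx$truth, N = 40, seed = 71, include_eta = FALSE)
  fit <- bsir(~ x, data = d$data, images = d$Y, basis = fx$basis,
              engine = "vi", standardize = FALSE, seed = 1)
  ppc <- posterior_predictive(fit, n_rep = 60, seed = 2)
  expect_gte(ppc$envelope_coverage, 0.9)
  expect_equal(dim(ppc$rep_density), c(60L, 512L))
  expect_error(posterior_predictive(fit, n_rep = 0), "at least 1")
  # simulate() returns replicate arrays of the data shape
  yr <- simulate(fit, nsim = 2, seed = 3)
  expect_equal(dim(yr), c(nrow(d$Y), fx$mask$V, 2L))
  # degenerate: zeroed parameters and variances give ~0 replicates
  fit0 <- fit
  q <- fit0$vi$q
  q$m_a[] <- 0; q$M_b[] <- 0; q$M_e[] <- 0
  q$S_a[] <- 0; q$S_b[] <- 0; q$S_eta[] <- 0
  q$sig$eps <- list(shape = 1e8, rate = 1e-4)   # E[sigma2] ~ 1e-12
  fit0$vi$q <- q
  expect_lt(max(abs(simulate(fit0, nsim = 1, seed = 4))), 1e-3)
})

test_that("fitted and residuals decompose the data", {
  fx <- fixture_sim()
  fit <- bsir(~ x, data = fx$d$data, images = fx$d$Y, basis = fx$basis,
              engine = "vi", standardize = FALSE, seed = 1)
  expect_equal(fitted(fit) + residuals(fit), fx$d$Y, tolerance = 1e-10,
               ignore_attr = TRUE)
  # in-sample fitted values with eta explain more variance than without
  r_no_eta <- fx$d$Y - predict(fit)
  expect_lt(mean(residuals(fit)^2), mean(r_no_eta^2))
})
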
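test_that("component density is the Gaussian it claims to be", {
  expect_equal(component_density(0, 0, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(component_density(3 + 0.7, 3, 2),
               component_density(3 - 0.7, 3, 2), tolerance = 1e-15)
  expect_equal(component_density(2, 0, 4), exp(-0.5) / sqrt(8 * pi),
               tolerance = 1e-12)
  expect_error(component_density(0, 0, -1), "kappa")
})

test_that("burst posterior matches the closed-form responsibility", {
  st <- gmm_state(0.5, 0, 10, 4, 4)
  expect_equal(posterior_burst_prob(5, st), 0.5, tolerance = 1e-12)
  st2 <- gmm_state(0.5, -50, 10, 1, 1)
  expect_gt(posterior_burst_prob(10 + 10, st2), 0.999)
  st3 <- gmm_state(0.3, 0, 10, 4, 4)
  expect_equal(posterior_burst_prob(6, st3),
               oracle_posterior(6, 0.7, 0.3, 0, 10, 4, 4), tolerance = 1e-12)
  # extreme observations resolve in the log domain, never NaN
  expect_false(is.nan(posterior_burst_prob(1e4, st)))
  expect_false(is.nan(posterior_burst_prob(-1e4, st)))
  expect_equal(posterior_burst_prob(1e4, st), 1)
})

test_that("single-Gaussian fit returns the closed-form MLE", {
  f <- em_fit(c(1, 2, 3, 1, 2, 3, 1, 2, 3, 2), 1)
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 2)
  expect_equal(f$state$mu, mean(x))
  expect_equal(f$state$kappa, mean((x - mean(x))^2))
  expect_equal(f$loglik, sum(dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)),
                                   log = TRUE)))
})

test_that("EM recovers a well-separated mixture and is monotone", {
  set.seed(11)
  x <- c(rnorm(700, 0, 1), rnorm(300, 10, 1))
  f <- em_fit(x, 2)
  expect_equal(f$state$mu0, 0, tolerance = 0.3)
  expect_equal(f$state$mu1, 10, tolerance = 0.3)
  expect_equal(f$state$w1, 0.3, tolerance = 0.05)
  expect_true(all(diff(f$loglik_trace) > -1e-8))
  expect_error(em_fit(rnorm(5), 2), "at least 10")
})

test_that("MDL picks one component on noise and two on separated mixtures", {
  set.seed(21)
  pick1 <- replicate(100, mdl_select(rnorm(80)))
  expect_gte(mean(pick1 == 1), 0.95)
  pick2 <- replicate(100, mdl_select(c(rnorm(40, 0, 1), rnorm(40, 12, 1))))
  expect_gte(mean(pick2 == 2), 0.95)
})

test_that("constraints enforce the burst/non-burst relationships", {
  cfg <- gmm_config()
  st <- gmm_state(0.4, 0, 1, 2, 2)      # gap 1 < delta
  out <- apply_constraints(st, cfg)
  expect_equal(out$mu1, 3.5)
  st2 <- gmm_state(0.001, 0, 10, 2, 3)  # weight below floor
  out2 <- apply_constraints(st2, cfg)
  expect_equal(out2$w1, 0.03)
  expect_equal(out2$w0, 0.97)
  # at the floor the burst component is the virtual one
  expect_equal(out2$mu1, out2$mu0 + 3.5)
  expect_equal(out2$kappa1, out2$kappa0)
  st3 <- gmm_state(0.4, 0, 10, 2, 1)    # burst variance below noise variance
  expect_equal(apply_constraints(st3, cfg)$kappa1, 2)
  # a state already satisfying everything is unchanged, and idempotent
  ok <- gmm_state(0.3, 0, 10, 2, 3)
  expect_equal(apply_constraints(ok, cfg), ok)
  expect_equal(apply_constraints(out, cfg), out)
})

test_that("sequential update equals the straight-line recursion", {
  cfg <- gmm_config()
  st <- gmm_state(0.3, 0, 10, 1, 1)
  out <- sequential_update(st, 10, cfg)
  want <- oracle_seq_update(st, 10, 0.99, 3.5, 0.03)
  for (f in names(want)) expect_equal(out[[f]], want[[f]], tolerance = 1e-12)
  set.seed(31)
  for (i in 1:50) {
    st <- random_constrained_state()
    x <- runif(1, st$mu0 - 5, st$mu1 + 5)
    out <- sequential_update(st, x, cfg)
    want <- oracle_seq_update(st, x, cfg$alpha, cfg$delta, cfg$epsilon)
    for (f in names(want)) expect_equal(out[[f]], want[[f]], tolerance = 1e-12)
  }
})

test_that("forgetting-factor limits behave as fixed points", {
  cfg1 <- gmm_config(alpha = 1)
  st <- gmm_state(0.3, 0, 10, 2, 3)
  expect_equal(sequential_update(st, 4, cfg1), st)
  # posterior equal to the weights leaves the weights unchanged
  st2 <- gmm_state(0.5, 0, 10, 4, 4)
  out <- sequential_update(st2, 5, gmm_config())  # posterior is exactly 0.5
  expect_equal(out$w1, 0.5, tolerance = 1e-12)
  expect_warning(out3 <- sequential_update(st2, NaN), "non-finite")
  expect_equal(out3, st2)
})

test_that("optimal threshold has its closed forms and is a Bayes minimizer", {
  expect_equal(optimal_threshold(gmm_state(0.5, 0, 10, 1, 1)), 5,
               tolerance = 1e-12)
  expect_equal(optimal_threshold(gmm_state(0.3, 0, 10, 1, 1)),
               5 + log(0.7 / 0.3) / 10, tolerance = 1e-12)
  expect_error(optimal_threshold(gmm_state(0.4, 5, 5, 1, 1)), "mu1 > mu0")
  set.seed(41)
  for (i in 1:50) {
    st <- random_constrained_state()
    g <- oracle_grid_threshold(st, step = 0.001)
    expect_true(g$interior)
    th <- optimal_threshold(st)
    # the analytic threshold never does worse than the grid minimum
    expect_lte(oracle_bayes_error(st, th), g$err + 1e-12)
    # where the error surface is resolvable the locations agree to about
    # one grid step; on underflow plateaus the grid argmin is arbitrary
    if (g$err > 1e-12) expect_lt(abs(th - g$theta), 2e-3)
  }
})

test_that("noise-only updates settle on the virtual component", {
  cfg <- gmm_config()
  set.seed(51)
  x <- rnorm(5000, mean = -3, sd = sqrt(2))
  st <- gmm_state(0.3, 0, 8, 1, 1)
  for (v in x) st <- sequential_update(st, v, cfg)
  expect_equal(st$mu0, -3, tolerance = 0.5)
  expect_gte(st$mu1 - st$mu0, cfg$delta)
  expect_gte(st$w1, cfg$epsilon)
})

test_that("sequential estimates agree with batch EM on stationary bimodal data", {
  cfg <- gmm_config()
  set.seed(61)
  x <- ifelse(runif(2000) < 0.3, rnorm(2000, 12, 1.5), rnorm(2000, 0, 1.5))
  batch <- em_fit(x, 2)$state
  st <- apply_constraints(em_fit(x[1:80], 2)$state, cfg)
  for (v in x[81:2000]) st <- sequential_update(st, v, cfg)
  expect_equal(st$mu0, batch$mu0, tolerance = 0.5)
  expect_equal(st$mu1, batch$mu1, tolerance = 0.5)
})
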
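test_that("absorption probabilities follow the closed form", {
  expect_equal(ddm_response_prob(wiener_params(a = 0.08, v = 0)), 0.5)
  expect_gt(ddm_response_prob(wiener_params(a = 0.08, v = 5, z = 0.079)),
            0.99)
  p <- wiener_params(a = 0.08, v = 0.3)
  expect_equal(ddm_response_prob(p, "upper") + ddm_response_prob(p, "lower"),
               1, tolerance = 1e-12)
  # reflection symmetry: upper(a, z, v) = lower(a, a - z, -v)
  expect_equal(ddm_response_prob(wiener_params(a = 0.09, z = 0.03, v = 0.4),
                                 "upper"),
               ddm_response_prob(wiener_params(a = 0.09, z = 0.06, v = -0.4),
                                 "lower"),
               tolerance = 1e-12)
})

test_that("absorption probability is strictly increasing in drift", {
  vs <- seq(-0.5, 0.5, by = 0.1)
  ps <- vapply(vs, function(v)
    ddm_response_prob(wiener_params(a = 0.08, v = v)), numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("upper-boundary probability matches a Monte-Carlo oracle", {
  set.seed(401)
  p <- wiener_params(a = 0.08, z = 0.04, v = 0.546)
  n <- 2e5
  sim <- sample_diffusion_trials(n, p, trial_variability(ter = 0))
  p_hat <- mean(sim$correct)
  p_an <- ddm_response_prob(p)
  se <- sqrt(p_an * (1 - p_an) / n)
  expect_lt(abs(p_hat - p_an), 3 * se)
})

test_that("first-passage density conserves mass and vanishes at t = 0", {
  p <- wiener_params(a = 0.063, v = 0.108)
  expect_equal(ddm_fpt_density(0, p, "upper"), 0)
  expect_equal(ddm_fpt_density(-1, p, "lower"), 0)
  expect_lt(ddm_fpt_density(1e-5, p, "upper"), 1e-10)
  I <- integrate(function(t) ddm_fpt_density(t, p, "upper") +
                   ddm_fpt_density(t, p, "lower"), 0, Inf, rel.tol = 1e-9)
  expect_equal(I$value, 1, tolerance = 1e-6)
})

test_that("density and CDF series representations agree", {
  # independent routes: numerically integrated density vs the series CDF
  for (par in list(wiener_params(a = 0.063, v = 0.108),
                   wiener_params(a = 0.106, v = 0.546),
                   wiener_params(a = 0.09, z = 0.03, v = -0.2))) {
    for (t0 in c(0.05, 0.2, 0.8)) {
      Fi <- integrate(function(t) ddm_fpt_density(t, par, "upper"),
                      0, t0, rel.tol = 1e-10)$value
      Fc <- ddm_defective_cdf(t0, par, trial_variability(ter = 0), "upper")
      expect_equal(Fi, Fc, tolerance = 1e-7)
    }
  }
})

test_that("simulated decision times match the analytic density (KS)", {
  set.seed(402)
  p <- wiener_params(a = 0.083, v = 0.283)
  n <- 2e5
  sim <- sample_diffusion_trials(n, p, trial_variability(ter = 0),
                                 dt = 2.5e-4)
  pu <- ddm_response_prob(p)
  Fcond <- function(t) {
    as.numeric(ddm_defective_cdf(t, p, trial_variability(ter = 0),
                                 "upper")) / pu
  }
  x <- sort(sim$rt[sim$correct == 1L])
  Fx <- Fcond(x)
  D <- max(abs(Fx - seq_along(x) / length(x)),
           abs(Fx - (seq_along(x) - 1) / length(x)))
  expect_lt(D, 0.01)
})

test_that("degenerate variability reduces to a time-shifted CDF", {
  p <- wiener_params(a = 0.063, v = 0.108)
  v0 <- trial_variability(eta = 0, sz = 0, ter = 0.3, st = 0)
  ts <- c(0.35, 0.5, 0.8, 2)
  shifted <- ddm_defective_cdf(ts, p, v0, "upper")
  base <- ddm_defective_cdf(ts - 0.3, p, trial_variability(ter = 0), "upper")
  expect_equal(shifted, base, tolerance = 1e-10)
})

test_that("no response mass before the minimum nondecision time", {
  p <- wiener_params(a = 0.063, v = 0.3)
  v <- trial_variability(eta = 0.18, sz = 0.03, ter = 0.35, st = 0.12)
  expect_equal(ddm_defective_cdf(c(0, 0.1, 0.28), p, v, "upper"),
               rep(0, 3))
  expect_equal(ddm_defective_cdf(c(0, 0.1, 0.28), p, v, "lower"),
               rep(0, 3))
})

test_that("defective CDF with variability matches the simulation oracle", {
  set.seed(403)
  w <- wiener_params(a = 0.106, v = 0.546)
  v <- trial_variability(eta = 0.184, sz = 0.037, ter = 0.414, st = 0.129)
  n <- 2e5
  sim <- sample_diffusion_trials(n, w, v, dt = 2.5e-4)
  ts <- c(0.45, 0.5, 0.6, 0.8, 1.0, 1.5, 2.0)
  for (bnd in c("upper", "lower")) {
    Fan <- ddm_defective_cdf(ts, w, v, bnd)
    emp <- vapply(ts, function(t0)
      mean(sim$rt <= t0 & sim$correct == (bnd == "upper")), numeric(1))
    se <- sqrt(pmax(Fan * (1 - Fan), 1e-8) / n)
    expect_true(all(abs(emp - Fan) < 3 * se + 1e-4))
  }
})

test_that("conservation and monotonicity hold over random parameter draws", {
  set.seed(404)
  for (i in 1:12) {
    ps <- random_param_set()
    up <- ddm_defective_cdf(Inf, ps$wiener, ps$var, "upper")
    lo <- ddm_defective_cdf(Inf, ps$wiener, ps$var, "lower")
    expect_equal(up + lo, 1, tolerance = 1e-4)
    ts <- sort(runif(15, 0.2, 3))
    Fu <- ddm_defective_cdf(ts, ps$wiener, ps$var, "upper")
    expect_true(all(diff(Fu) >= -1e-12))
    expect_true(all(Fu >= 0 & Fu <= up + 1e-10))
  }
})

test_that("invalid parameters are rejected", {
  expect_error(wiener_params(a = -0.1, v = 0.2), "positive")
  expect_error(wiener_params(a = 0.08, v = 0.2, z = 0.08), "0 < z < a")
  expect_error(trial_variability(eta = -1), ">= 0")
  expect_error(trial_variability(st = 0.2, ter = 0.05), "st")
  # starting-point range reaching a boundary
  p <- wiener_params(a = 0.06, v = 0.1)
  v <- trial_variability(sz = 0.06, ter = 0.3)
  expect_error(ddm_defective_cdf(0.5, p, v, "upper"), "boundary")
})
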
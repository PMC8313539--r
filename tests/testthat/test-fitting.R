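test_that("quantiles use linear interpolation and behave on edge cases", {
  expect_equal(compute_quantiles(1:10, 0.5), 5.5)
  expect_equal(compute_quantiles(rep(3.2, 50)), rep(3.2, 9))
  expect_true(!is.unsorted(compute_quantiles(rexp(100))))
  expect_error(compute_quantiles(1:5), "single-bin")
  # large-sample quantile matches the normal inverse CDF
  set.seed(601)
  x <- rnorm(1e5)
  expect_lt(abs(compute_quantiles(x, 0.1) - qnorm(0.1)), 0.02)
})

test_that("G-square matches direct arithmetic and scales linearly in N", {
  expect_equal(gsquare(c(0.5, 0.5), c(0.5, 0.5), 100), 0)
  g <- 200 * (0.5 * log(0.5 / 0.6) + 0.5 * log(0.5 / 0.4))
  expect_equal(gsquare(c(0.5, 0.5), c(0.6, 0.4), 100), g)
  expect_equal(gsquare(c(0.5, 0.5), c(0.6, 0.4), 200), 2 * g)
  expect_gt(gsquare(c(0.3, 0.7), c(0.5, 0.5), 50), 0)
  # observed-empty bins contribute nothing
  expect_equal(gsquare(c(0, 1), c(0.5, 0.5), 10), 2 * 10 * log(1 / 0.5))
  expect_warning(gsquare(c(0.5, 0.5), c(1e-12, 1 - 1e-12), 10),
                 "near-zero")
  expect_error(gsquare(c(0.7, 0.7), c(0.5, 0.5), 10), "sum to 1")
})

test_that("quantile summaries bin each response into tenths", {
  d <- tiny_dataset(seed = 31, n = 60)
  qs <- quantile_summary(d, fit_config())
  expect_length(qs, 25L)
  for (cell in qs) {
    expect_equal(sum(cell$p), 1, tolerance = 1e-12)
    expect_equal(cell$n_correct + cell$n_error, cell$N)
    if (!is.null(cell$edges_c)) {
      expect_length(cell$edges_c, 9L)
      expect_true(!is.unsorted(cell$edges_c))
    }
  }
  # sparse error cells fall back to a single bin
  sparse <- Filter(function(cell) cell$n_error < 11, qs)
  expect_gt(length(sparse), 0)
  expect_true(all(vapply(sparse, function(cell) is.null(cell$edges_e),
                         logical(1))))
  # missing cells are an input error
  expect_error(quantile_summary(d[d$speed_cond != 3, ], fit_config()),
               "no trials")
})

test_that("parameter transform round-trips and respects constraints", {
  for (tie in c(TRUE, FALSE)) {
    for (free in list(rep(TRUE, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))) {
      spec <- ddmix:::par_spec(tie, free)
      d0 <- canonical
      d0$p_o[!free] <- 0
      if (tie) { d0$a[1] <- d0$a[2]; d0$ter[1] <- d0$ter[2] }
      theta <- ddmix:::encode_design(d0, spec)
      expect_length(theta, spec$n)
      d1 <- ddmix:::decode_theta(theta, spec)
      expect_equal(d1$a, d0$a, tolerance = 1e-8)
      expect_equal(d1$ter, d0$ter, tolerance = 1e-8)
      expect_equal(d1$p_o, d0$p_o, tolerance = 1e-3)
      expect_equal(d1$v, d0$v, tolerance = 1e-8)
      expect_lt(d1$sz, min(d1$a))
      expect_lte(d1$st, 2 * min(d1$ter))
    }
  }
  # the headline parameter count of the untied, all-free design is 25
  expect_equal(ddmix:::par_spec(FALSE, rep(TRUE, 5))$n, 25L)
  # tying a and ter across the two fastest conditions removes 2
  expect_equal(ddmix:::par_spec(TRUE, rep(TRUE, 5))$n, 23L)
})

test_that("the generating design scores lower than perturbed designs", {
  d <- tiny_dataset(seed = 41, n = 120)
  cfg <- fit_config()
  cells <- quantile_summary(d, cfg)
  g_true <- ddmix:::design_gsquare(canonical, cells, cfg)
  worse <- canonical
  worse$v <- canonical$v * 1.6
  worse$p_o <- pmin(canonical$p_o + 0.15, 1)
  g_worse <- ddmix:::design_gsquare(worse, cells, cfg)
  expect_lt(g_true, g_worse)
})

test_that("moment-based starting heuristics land near the generating values", {
  d <- tiny_dataset(seed = 51, n = 200)
  start <- ddmix:::start_heuristic(d, fit_config())
  expect_s3_class(start, "design_params")
  expect_lt(abs(start$p_o[1] - 0.735), 0.25)
  expect_lt(start$p_o[5], 0.1)
  expect_lt(abs(start$mu_g - 0.262), 0.05)
  expect_true(all(start$ter > 0.15 & start$ter < 0.8))
})

test_that("a budgeted fit applies the zeroing rule and improves on the start", {
  d <- tiny_dataset(seed = 61, n = 40)
  cfg <- fit_config(restarts = 0, maxit = 300, seed = 2)
  fit <- fit_subject(d, cfg)
  expect_s3_class(fit, "ddmix_fit")
  # conditions generated without guessing end at exactly zero
  expect_true(all(fit$design$p_o[3:5] == 0))
  expect_true(any(fit$modifications$po_zeroed))
  expect_true(fit$modifications$tied_fast_conditions)
  expect_true(is.finite(fit$gsquare))
  # releasing the frozen variability parameters never worsens the objective
  # (zeroing p_o afterwards constrains the model, so the final value may
  # legitimately sit above the unconstrained stage-2 optimum)
  expect_lte(fit$trace[["stage2"]], fit$trace[["stage1"]] + 1e-8)
  # deterministic given the config seed
  fit2 <- fit_subject(d, cfg)
  expect_equal(fit$gsquare, fit2$gsquare)
  expect_equal(fit$design$p_o, fit2$design$p_o)
})

test_that("degrees-of-freedom bookkeeping follows the quantile design", {
  g <- goodness_of_fit(654.4)
  expect_equal(g$df, 450)
  expect_equal(round(g$critical_value, 1), 500.5)
  expect_equal(g$grade, "good")       # between 1x and 2x the critical value
  expect_equal(goodness_of_fit(0)$grade, "good")
  expect_equal(goodness_of_fit(1200)$grade, "poor")
  # 25 cells x (20 bins - 1) data degrees of freedom
  expect_equal(475L, 25L * 19L)
})
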
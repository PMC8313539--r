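test_that("guess trials have the right latency distribution and accuracy", {
  set.seed(501)
  g <- guess_params(p_o = 1, mu_g = 0.262, s_g = 0.051)
  n <- 1e5
  d <- sample_guess_trials(n, g)
  expect_lt(abs(mean(d$rt) - 0.262), 3 * 0.051 / sqrt(n))
  expect_lt(abs(mean(d$correct) - 0.5), 0.005)
  expect_true(all(d$rt > 0))
  # degenerate spread pins every latency to the mean
  d0 <- sample_guess_trials(1000, guess_params(p_o = 1, mu_g = 0.262,
                                               s_g = 1e-6))
  expect_true(all(abs(d0$rt - 0.262) < 1e-4))
})

test_that("diffusion sampler respects symmetry and the nondecision floor", {
  set.seed(502)
  p <- wiener_params(a = 0.08, v = 0)
  v <- trial_variability(eta = 0, sz = 0, ter = 0.3, st = 0.1)
  n <- 1e5
  d <- sample_diffusion_trials(n, p, v)
  expect_lt(abs(mean(d$correct) - 0.5), 3 * 0.5 / sqrt(n))
  expect_gte(min(d$rt), 0.3 - 0.05)
})

test_that("diffusion sampler accuracy matches the analytic asymptote", {
  set.seed(503)
  cond <- slow_cell()
  n <- 1e5
  d <- sample_diffusion_trials(n, cond$wiener, cond$var)
  p_an <- ddm_defective_cdf(Inf, cond$wiener, cond$var, "upper")
  se <- sqrt(p_an * (1 - p_an) / n)
  expect_lt(abs(mean(d$correct) - p_an), 3 * se)
})

test_that("simulate_dataset produces a balanced, labeled, seeded design", {
  d1 <- tiny_dataset(seed = 77)
  d2 <- tiny_dataset(seed = 77)
  expect_identical(d1, d2)                      # determinism
  expect_equal(nrow(d1), 25 * 40)
  counts <- table(d1$speed_cond, d1$contrast_cond)
  expect_true(all(counts == 40))
  expect_true(all(d1$rt > 0))
  expect_setequal(unique(d1$origin), c("guess", "diffusion"))
  # guesses are marked only where p_o > 0
  expect_true(all(d1$origin[d1$speed_cond >= 3] == "diffusion"))
  # a single subject at 200 trials/cell gives ~5000 observations
  expect_equal(25 * 200, 5000)
})

test_that("per-cell guess fractions converge to p_o", {
  set.seed(504)
  d <- simulate_dataset(canonical, n_subjects = 1, n_trials_per_cell = 400,
                        seed = 88, between_subject_sd = 0)
  frac <- tapply(d$origin == "guess", d$speed_cond, mean)
  for (sp in 1:5) {
    p <- canonical$p_o[sp]
    se <- sqrt(max(p * (1 - p), 1e-12) / 2000)
    expect_lt(abs(frac[[sp]] - p), 3 * se + 1e-12)
  }
})

test_that("all-zero guess probabilities yield pure diffusion data", {
  d0 <- design_params(a = canonical$a, ter = canonical$ter,
                      p_o = rep(0, 5), v = canonical$v, eta = canonical$eta,
                      sz = canonical$sz, st = canonical$st,
                      mu_g = canonical$mu_g, s_g = canonical$s_g)
  d <- simulate_dataset(d0, n_subjects = 1, n_trials_per_cell = 10,
                        seed = 5, between_subject_sd = 0)
  expect_true(all(d$origin == "diffusion"))
})

test_that("between-subject perturbation keeps designs valid and zeros fixed", {
  set.seed(505)
  for (i in 1:10) {
    pd <- ddmix:::perturb_design(canonical, 0.1)
    expect_s3_class(pd, "design_params")
    expect_true(all(pd$p_o[3:5] == 0))
    expect_lt(pd$sz, min(pd$a))
  }
})

test_that("synthetic data reproduce the qualitative empirical signatures", {
  d <- simulate_dataset(canonical, n_subjects = 1, n_trials_per_cell = 400,
                        seed = 99, between_subject_sd = 0)
  # bimodal speeded RT histogram: mass both below and well above 300 ms
  rt1 <- d$rt[d$speed_cond == 1]
  expect_gt(mean(rt1 < 0.3), 0.5)
  expect_gt(mean(rt1 > 0.4), 0.1)
  # chance accuracy below 300 ms, real accuracy above
  expect_lt(abs(mean(d$correct[d$speed_cond == 1 & d$rt < 0.3]) - 0.5), 0.03)
  expect_gt(mean(d$correct[d$speed_cond == 5]), 0.75)
  # error-vs-correct RT sign flip across speed stress
  dif <- error_correct_rt_diff(d)
  expect_lt(dif[1], 0)
  expect_gt(dif[5], 0)
})
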
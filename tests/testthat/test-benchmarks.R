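test_that("error-correct RT difference is zero for identical distributions", {
  rt <- rep(seq(0.3, 1, length.out = 50), 2)
  tr <- data.frame(subject = 1, speed_cond = rep(1:5, each = 100, length.out = 100),
                   contrast_cond = 1, correct = rep(0:1, each = 50),
                   rt = rt)
  tr$speed_cond <- 1
  expect_equal(unname(error_correct_rt_diff(tr)[1]), 0)
  # absent response type gives an undefined marker
  tr2 <- tr[tr$correct == 1, ]
  expect_true(is.na(error_correct_rt_diff(tr2)[1]))
})

test_that("CV is scale-invariant and matches the exponential closed form", {
  set.seed(701)
  x <- rexp(1e5)
  expect_lt(abs(cv_ratio(x) - 1), 0.02)
  expect_equal(cv_ratio(3 * x), cv_ratio(x))
  expect_equal(cv_ratio(rep(2, 10)), 0)
  expect_true(is.na(cv_ratio(1)))
})

test_that("skewness measures match closed forms and symmetry", {
  set.seed(702)
  x <- rexp(1e5)
  sk <- skewness_measures(x)
  expect_lt(abs(sk[["moment"]] - 2), 0.1)
  expect_gt(sk[["quartile"]], 0)
  sym <- c(-3, -1, 0, 1, 3)
  sks <- skewness_measures(sym)
  expect_equal(unname(sks), c(0, 0, 0), tolerance = 1e-12)
  expect_true(is.na(skewness_measures(c(1, 1, 1, 1, 1, 5))[["quartile"]]))
  expect_error(skewness_measures(1:3), "at least 4")
})

test_that("benchmark signatures from canonical simulation match expectations", {
  d <- simulate_dataset(canonical, n_subjects = 1, n_trials_per_cell = 400,
                        seed = 21, between_subject_sd = 0)
  b <- benchmark_table(d, mode = "pooled")
  expect_lt(b$err_minus_corr[1], 0)
  expect_gt(b$err_minus_corr[5], 0)
  # U shapes: an interior speed condition minimizes CV and moment skewness
  expect_lt(min(b$cv[2:4]), min(b$cv[1], b$cv[5]))
  expect_lt(min(b$skew_moment[2:4]), min(b$skew_moment[1], b$skew_moment[5]))
  # per-subject averaging agrees with pooled for a single subject
  b2 <- benchmark_table(d, mode = "per_subject")
  expect_equal(b2$cv, b$cv)
})

test_that("upper cutoffs disturb SD and moment skewness but not quartile skewness", {
  set.seed(703)
  cond <- slow_cell()
  base <- ddmix:::simulate_condition(2e4, cond)$rt
  # contaminate with 2% slow outliers between 2 and 5 s
  n_out <- 400
  rts <- c(base, runif(n_out, 2, 5))
  cut <- function(x, hi) x[x < hi]
  sd_change <- abs(sd(cut(rts, 5)) / sd(cut(rts, 2)) - 1)
  mom_change <- abs(skewness_measures(cut(rts, 5))[["moment"]] /
                      skewness_measures(cut(rts, 2))[["moment"]] - 1)
  qrt_change <- abs(skewness_measures(cut(rts, 5))[["quartile"]] -
                      skewness_measures(cut(rts, 2))[["quartile"]])
  expect_gt(sd_change, 0.1)
  expect_gt(mom_change, 0.3)
  expect_lt(qrt_change, 0.05)
})

test_that("chance-accuracy test recovers t-test machinery exactly", {
  set.seed(704)
  # identical per-subject accuracies of exactly 0.5 give t = 0, p = 1
  tr <- do.call(rbind, lapply(1:6, function(s)
    data.frame(subject = s, speed_cond = 1, contrast_cond = 1,
               correct = rep(0:1, 10), rt = runif(20, 0.1, 0.25))))
  ct <- chance_accuracy_test(tr)
  expect_equal(ct$t, 0)
  expect_equal(ct$p, 1)
  # cross-check against stats::t.test on simulated heterogeneous data
  d <- simulate_dataset(canonical, n_subjects = 8, n_trials_per_cell = 30,
                        seed = 15, between_subject_sd = 0.1)
  ct2 <- chance_accuracy_test(d)
  ref <- t.test(as.numeric(ct2$subject_means), mu = 0.5)
  expect_equal(ct2$t, unname(ref$statistic))
  expect_equal(ct2$p, ref$p.value)
  expect_equal(ct2$df, unname(ref$parameter))
})

test_that("subjects without qualifying trials are excluded with a message", {
  tr <- data.frame(subject = rep(1:3, each = 20),
                   speed_cond = 1, contrast_cond = 1,
                   correct = rep(0:1, 30),
                   rt = c(runif(40, 0.1, 0.25), runif(20, 0.5, 1)))
  expect_message(ct <- chance_accuracy_test(tr), "excluded")
  expect_equal(ct$n_subjects, 2)
  expect_equal(ct$excluded, "3")
})

test_that("QPP tables apply the sparse-cell median rule", {
  set.seed(705)
  d <- tiny_dataset(seed = 71, n = 60)
  tab <- qpp_table(d)
  expect_true(all(tab$summary[tab$n > 15] == "quantiles"))
  expect_true(all(tab$summary[tab$n <= 15] == "median"))
  med_rows <- tab[tab$summary == "median", ]
  if (nrow(med_rows)) {
    expect_true(all(is.na(med_rows$q10)))
    expect_true(all(is.finite(med_rows$q50)))
  }
  full <- tab[tab$summary == "quantiles", ]
  expect_true(all(full$q10 <= full$q30 & full$q30 <= full$q50 &
                    full$q50 <= full$q70 & full$q70 <= full$q90))
  # proportions of the two response types sum to 1 within each cell
  agg <- tapply(tab$prop, paste(tab$speed_cond, tab$contrast_cond), sum)
  expect_true(all(abs(agg - 1) < 1e-12))
})

test_that("model-side QPP proportions obey the mixture identity", {
  tab <- qpp_model_table(canonical)
  for (sp in c(1, 5)) for (co in c(1, 5)) {
    cond <- design_cell(canonical, sp, co)
    row <- tab[tab$speed_cond == sp & tab$contrast_cond == co &
                 tab$response == "correct", ]
    expect_equal(row$prop, mixture_accuracy(cond), tolerance = 1e-6)
    expect_true(all(diff(as.numeric(row[paste0("q", c(10, 30, 50, 70, 90))])) > 0))
  }
})
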
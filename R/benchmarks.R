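#' Mean error RT minus mean correct RT
#'
#' The signed latency difference between error and correct responses, per
#' speed condition (collapsed over contrast).  Under heavy fast-guess
#' contamination errors are dominated by fast guesses and the difference is
#' negative; with accuracy stress, across-trial drift variability makes
#' errors slower than correct responses and the difference turns positive.
#'
#' @param trials trial data.frame (columns `speed_cond`, `correct`, `rt`).
#' @return Named numeric vector of differences (seconds) for speed
#'   conditions 1-5; `NA` where a condition lacks one of the response types.
#' @export
error_correct_rt_diff <- function(trials) {
  vapply(1:5, function(sp) {
    sel <- trials$speed_cond == sp
    e <- trials$rt[sel & trials$correct == 0L]
    c_ <- trials$rt[sel & trials$correct == 1L]
    if (!length(e) || !length(c_)) return(NA_real_)
    mean(e) - mean(c_)
  }, numeric(1)) |> stats::setNames(paste0("speed", 1:5))
}

#' Coefficient of variation of RTs
#'
#' SD divided by mean; scale-invariant, so it isolates distribution shape
#' from overall speed.
#'
#' @param rts numeric RT sample.
#' @return SD/mean, or `NA` for fewer than 2 observations.
#' @export
cv_ratio <- function(rts) {
  if (length(rts) < 2L) return(NA_real_)
  sd(rts) / mean(rts)
}

#' Skewness measures for RT distributions
#'
#' Three measures of asymmetry: the moment skewness (third standardized
#' central moment), which is notoriously outlier-sensitive for RTs; the
#' quartile skewness \eqn{(Q_3 + Q_1 - 2 Q_2) / (Q_3 - Q_1)}, bounded in
#' `[-1, 1]`; and Pearson's skewness \eqn{3(\mathrm{mean} -
#' \mathrm{median})/\mathrm{SD}}.  The robust measures are preferable when
#' distributions may be contaminated or truncated by cutoffs.
#'
#' @param rts numeric RT sample with at least 4 observations.
#' @return Named vector `c(moment, quartile, pearson)`; quartile skewness is
#'   `NA` when the interquartile range is zero.
#' @export
skewness_measures <- function(rts) {
  if (length(rts) < 4L)
    stop("need at least 4 observations", call. = FALSE)
  m <- mean(rts)
  s2 <- mean((rts - m)^2)
  moment <- mean((rts - m)^3) / s2^1.5
  q <- quantile(rts, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  quart <- if (iqr > 0) (q[3] + q[1] - 2 * q[2]) / iqr else NA_real_
  pearson <- 3 * (m - median(rts)) / sqrt(s2)
  c(moment = moment, quartile = quart, pearson = pearson)
}

#' Benchmark statistics per speed condition
#'
#' The three benchmark statistics used to characterize speed-accuracy
#' tradeoff data — mean error RT minus mean correct RT, SD/mean, and RT
#' skewness (moment, quartile, and Pearson variants) — per speed condition,
#' collapsed over contrast.  Correct and error RTs are pooled for the CV and
#' skewness measures.  In `"per_subject"` mode each statistic is computed
#' for every subject separately and then averaged (the default; aggregation
#' order matters for these nonlinear statistics); `"pooled"` computes them
#' on all trials at once.
#'
#' @param trials trial data.frame (columns `subject`, `speed_cond`,
#'   `correct`, `rt`).
#' @param mode `"per_subject"` or `"pooled"`.
#' @return A data.frame with one row per speed condition: `n`,
#'   `err_minus_corr`, `cv`, `skew_moment`, `skew_quartile`, `skew_pearson`.
#' @export
benchmark_table <- function(trials, mode = c("per_subject", "pooled")) {
  mode <- match.arg(mode)
  one <- function(tr) {
    dif <- error_correct_rt_diff(tr)
    t(vapply(1:5, function(sp) {
      rts <- tr$rt[tr$speed_cond == sp]
      sk <- if (length(rts) >= 4L) skewness_measures(rts)
            else c(moment = NA_real_, quartile = NA_real_,
                   pearson = NA_real_)
      c(err_minus_corr = unname(dif[sp]), cv = cv_ratio(rts), sk)
    }, numeric(5)))
  }
  n <- vapply(1:5, function(sp) sum(trials$speed_cond == sp), integer(1))
  m <- if (mode == "pooled") {
    one(trials)
  } else {
    subs <- unique(trials$subject)
    arr <- vapply(subs, function(s) one(trials[trials$subject == s, , drop = FALSE]),
                  matrix(0, 5, 5))
    apply(arr, c(1, 2), mean, na.rm = TRUE)
  }
  data.frame(speed_cond = 1:5, n = n, err_minus_corr = m[, 1], cv = m[, 2],
             skew_moment = m[, 3], skew_quartile = m[, 4],
             skew_pearson = m[, 5])
}

#' Chance-accuracy test for fast responses
#'
#' Tests whether responses faster than `rt_cutoff` are at chance accuracy: a
#' two-tailed one-sample t-test of per-subject mean accuracy against 0.5,
#' with Cohen's d computed as the absolute mean deviation from 0.5 divided
#' by the between-subject SD.  Fast guesses carry no stimulus information,
#' so under heavy guessing the sub-cutoff accuracy should be
#' indistinguishable from 0.5.
#'
#' @param trials trial data.frame (columns `subject`, `speed_cond`,
#'   `correct`, `rt`).
#' @param rt_cutoff RT cutoff in seconds (responses strictly faster are
#'   analyzed); the default 0.3 s is where accuracy typically starts to
#'   rise above chance in heavily speeded data.
#' @param speed speed condition(s) to include.
#' @return A list: `t`, `df`, `p` (two-tailed), `cohens_d`,
#'   `subject_means`, `n_subjects`, `excluded` (subjects with no qualifying
#'   trials).
#' @export
chance_accuracy_test <- function(trials, rt_cutoff = 0.3, speed = 1) {
  sel <- trials$speed_cond %in% speed & trials$rt < rt_cutoff
  sub <- trials[sel, , drop = FALSE]
  means <- tapply(sub$correct, sub$subject, mean)
  all_subj <- unique(trials$subject)
  excluded <- setdiff(as.character(all_subj), names(means))
  if (length(excluded))
    message("excluded subject(s) with no qualifying trials: ",
            paste(excluded, collapse = ", "))
  acc <- as.numeric(means)
  if (length(acc) < 2L)
    stop("need at least 2 subjects with qualifying trials", call. = FALSE)
  n <- length(acc)
  sd_acc <- sd(acc)
  tstat <- if (sd_acc == 0) {
    if (mean(acc) == 0.5) 0 else sign(mean(acc) - 0.5) * Inf
  } else (mean(acc) - 0.5) / (sd_acc / sqrt(n))
  list(t = tstat, df = n - 1L, p = pvalue_from_t(tstat, n - 1L),
       cohens_d = if (sd_acc == 0) { if (mean(acc) == 0.5) 0 else Inf }
                  else abs(mean(acc) - 0.5) / sd_acc,
       subject_means = means, n_subjects = n, excluded = excluded)
}

# two-tailed p-value of a t statistic
pvalue_from_t <- function(tstat, df) 2 * pt(-abs(tstat), df)

#' Quantile-probability-plot table from trial data
#'
#' For every design cell and response type: the response proportion and the
#' 0.1, 0.3, 0.5, 0.7, 0.9 RT quantiles, the standard summary behind
#' quantile probability plots.  Response types with `min_n` or fewer
#' observations report the median only (quantile estimates are unstable in
#' sparse cells); empty response types are omitted.
#'
#' @param trials trial data.frame.
#' @param min_n sparse-cell threshold: full quantiles require strictly more
#'   observations than this.
#' @return A data.frame with columns `speed_cond`, `contrast_cond`,
#'   `response`, `n`, `prop`, `summary` (`"quantiles"` or `"median"`), and
#'   `q10`, `q30`, `q50`, `q70`, `q90` (only `q50` filled for median-only
#'   rows).
#' @export
qpp_table <- function(trials, min_n = 15) {
  check_trials(trials)
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  rows <- list()
  for (sp in 1:5) for (co in 1:5) {
    sel <- trials$speed_cond == sp & trials$contrast_cond == co
    N <- sum(sel)
    if (N == 0L) next
    for (resp in c("correct", "error")) {
      rts <- trials$rt[sel & trials$correct == (resp == "correct")]
      n <- length(rts)
      if (n == 0L) next
      if (n > min_n) {
        qs <- quantile(rts, probs, type = 7, names = FALSE)
        summ <- "quantiles"
      } else {
        qs <- c(NA, NA, median(rts), NA, NA)
        summ <- "median"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        speed_cond = sp, contrast_cond = co, response = resp, n = n,
        prop = n / N, summary = summ, q10 = qs[1], q30 = qs[2], q50 = qs[3],
        q70 = qs[4], q90 = qs[5])
    }
  }
  do.call(rbind, rows)
}

#' Model-predicted quantile-probability-plot table
#'
#' The model-side counterpart of [qpp_table()]: for every design cell and
#' response type, the predicted response probability and the RT quantiles
#' of the conditional (response-given) mixture distribution, obtained by
#' numerically inverting the mixture defective CDF.
#'
#' @param design a [design_params()] object.
#' @param probs quantile probabilities to report.
#' @return A data.frame analogous to [qpp_table()] output.
#' @export
qpp_model_table <- function(design, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  stopifnot(inherits(design, "design_params"))
  rows <- list()
  for (sp in 1:5) for (co in 1:5) {
    cond <- design_cell(design, sp, co)
    for (resp in c("correct", "error")) {
      ptot <- mixture_defective_cdf(Inf, cond, resp)
      qs <- vapply(probs, function(p) {
        target <- p * ptot
        uniroot(function(t) mixture_defective_cdf(t, cond, resp) - target,
                interval = c(1e-3, 20), tol = 1e-6)$root
      }, numeric(1))
      row <- data.frame(speed_cond = sp, contrast_cond = co,
                        response = resp, prop = ptot)
      row[paste0("q", round(100 * probs))] <- as.list(qs)
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
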
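#' Sample fast-guess trials
#'
#' Draws guess latencies from the zero-truncated normal guess distribution
#' and assigns correctness by a fair coin (guesses carry no stimulus
#' information).
#'
#' @param n number of trials.
#' @param guess a [guess_params()] object.
#' @return A data.frame with columns `rt` (seconds) and `correct` (0/1).
#' @export
sample_guess_trials <- function(n, guess) {
  stopifnot(inherits(guess, "guess_params"), n >= 0)
  rt <- rnorm(n, guess$mu_g, guess$s_g)
  bad <- which(rt <= 0)
  while (length(bad)) {                       # rejection step; ~never loops
    rt[bad] <- rnorm(length(bad), guess$mu_g, guess$s_g)
    bad <- bad[rt[bad] <= 0]
  }
  data.frame(rt = rt, correct = rbinom(n, 1L, 0.5))
}

#' Sample diffusion trials
#'
#' Simulates diffusion decisions by Euler-Maruyama integration of the
#' evidence path with a Brownian-bridge boundary-crossing correction, which
#' removes the leading-order discretization bias in absorption probabilities
#' and passage times.  Across-trial variability (drift, starting point,
#' nondecision time) is drawn per trial.  Uses R's RNG, so results are
#' reproducible under [set.seed()].
#'
#' @param n number of trials.
#' @param wiener a [wiener_params()] object.
#' @param var a [trial_variability()] object.
#' @param dt Euler time step in seconds.
#' @return A data.frame with columns `rt` (decision plus nondecision time,
#'   seconds) and `correct` (1 = upper boundary).
#' @export
sample_diffusion_trials <- function(n, wiener, var, dt = 5e-4) {
  stopifnot(inherits(wiener, "wiener_params"),
            inherits(var, "trial_variability"), n >= 0, dt > 0)
  check_sz(wiener, var)
  sim <- sim_wiener_cpp(as.integer(n), wiener$a, wiener$z, wiener$v,
                        wiener$s, var$eta, var$sz, var$ter, var$st, dt)
  data.frame(rt = sim$rt, correct = as.integer(sim$upper))
}

# One design cell of the mixture: per-trial Bernoulli(p_o) choice between
# the guess and diffusion processes, preserving trial order.
simulate_condition <- function(n, cond, dt = 5e-4) {
  is_guess <- runif(n) < cond$guess$p_o
  rt <- numeric(n); correct <- integer(n)
  ng <- sum(is_guess)
  if (ng > 0) {
    g <- sample_guess_trials(ng, cond$guess)
    rt[is_guess] <- g$rt; correct[is_guess] <- g$correct
  }
  if (ng < n) {
    d <- sample_diffusion_trials(n - ng, cond$wiener, cond$var, dt)
    rt[!is_guess] <- d$rt; correct[!is_guess] <- d$correct
  }
  data.frame(rt = rt, correct = correct,
             origin = ifelse(is_guess, "guess", "diffusion"))
}

# Multiplicative log-normal perturbation of a design for between-subject
# heterogeneity.  Zero guess probabilities stay exactly zero; ranges are
# re-clipped so every cell remains valid.
perturb_design <- function(design, sdlog) {
  jit <- function(x) x * exp(rnorm(length(x), 0, sdlog))
  a <- jit(design$a); ter <- jit(design$ter); v <- jit(design$v)
  p_o <- pmin(jit(design$p_o), 0.98)
  eta <- jit(design$eta)
  mu_g <- jit(design$mu_g); s_g <- jit(design$s_g)
  sz <- min(jit(design$sz), 0.95 * min(a))
  st <- min(jit(design$st), 1.9 * min(ter))
  design_params(a = a, ter = ter, p_o = p_o, v = v, eta = eta, sz = sz,
                st = st, mu_g = mu_g, s_g = s_g, s = design$s)
}

#' Simulate a full synthetic experiment
#'
#' Generates per-trial choice-RT data with the structure of a heavily
#' speed-stressed 5 (speed-accuracy) x 5 (contrast) experiment: a balanced
#' design with `n_trials_per_cell` trials in each of the 25 cells per
#' subject (the default 200 gives 5000 trials per subject).  Each trial is a
#' fast guess with the cell's probability `p_o`, otherwise a diffusion
#' decision.  Optionally, each subject's parameters are perturbed by a
#' multiplicative log-normal factor (`between_subject_sd` on the log scale)
#' to emulate between-subject heterogeneity; the canonical design values are
#' then population means.  The latent `origin` column records which process
#' generated each trial.
#'
#' Trials are generated subject-major under a single seeded stream, so a
#' fixed `seed` makes the full dataset reproducible.
#'
#' @param design a [design_params()] object; defaults to [default_design()].
#' @param n_subjects number of subjects.
#' @param n_trials_per_cell trials per design cell and subject.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param between_subject_sd SD of the log-normal between-subject parameter
#'   perturbation; 0 gives identical subjects at the design values.
#' @param dt Euler step for the diffusion simulation, seconds.
#' @return A data.frame with columns `subject`, `speed_cond`,
#'   `contrast_cond`, `correct`, `rt`, `origin`.
#' @examples
#' d <- simulate_dataset(n_subjects = 1, n_trials_per_cell = 10, seed = 1)
#' nrow(d)  # 250
#' @export
simulate_dataset <- function(design = default_design(), n_subjects = 20,
                             n_trials_per_cell = 200, seed = NULL,
                             between_subject_sd = 0.1, dt = 5e-4) {
  stopifnot(inherits(design, "design_params"), n_subjects >= 1,
            n_trials_per_cell >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_subjects * 25L)
  k <- 0L
  for (subj in seq_len(n_subjects)) {
    dsub <- if (between_subject_sd > 0) perturb_design(design, between_subject_sd)
            else design
    for (sp in 1:5) for (co in 1:5) {
      cond <- design_cell(dsub, sp, co)
      cell <- simulate_condition(n_trials_per_cell, cond, dt)
      k <- k + 1L
      out[[k]] <- data.frame(subject = subj, speed_cond = sp,
                             contrast_cond = co, correct = cell$correct,
                             rt = cell$rt, origin = cell$origin)
    }
  }
  do.call(rbind, out)
}
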
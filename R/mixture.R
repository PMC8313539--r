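# CDF of the guess latency distribution: normal truncated at zero and
# renormalized (RTs cannot be negative; for realistic parameters the
# truncated mass is < 1e-6).
guess_cdf <- function(t, guess) {
  p0 <- pnorm(0, guess$mu_g, guess$s_g)
  out <- (pnorm(t, guess$mu_g, guess$s_g) - p0) / (1 - p0)
  out[t <= 0] <- 0
  pmin(pmax(out, 0), 1)
}

guess_pdf <- function(t, guess) {
  p0 <- pnorm(0, guess$mu_g, guess$s_g)
  out <- dnorm(t, guess$mu_g, guess$s_g) / (1 - p0)
  out[t <= 0] <- 0
  out
}

#' Defective CDF of the diffusion/fast-guess mixture
#'
#' Cumulative probability of a correct (or error) response by time `t` under
#' the mixture model: with probability `p_o` the trial is a fast guess
#' (latency normal with mean `mu_g`, SD `s_g`, truncated at zero; accuracy
#' exactly 50%), otherwise it is a diffusion decision.  For response
#' \eqn{r}, \deqn{F_r(t) = p_o \cdot 0.5 \cdot \Phi_g(t) +
#' (1 - p_o) F^{\mathrm{diff}}_r(t).}
#' The correct response corresponds to the upper boundary of the diffusion
#' process.
#'
#' @param t response times in seconds; `Inf` gives the total probability of
#'   the response.
#' @param cond a [condition_params()] object.
#' @param response `"correct"` or `"error"`.
#' @param n_gh,n_gl quadrature orders passed to [ddm_defective_cdf()].
#' @return Vector of cumulative probabilities.
#' @export
mixture_defective_cdf <- function(t, cond, response = c("correct", "error"),
                                  n_gh = 20, n_gl = 10) {
  stopifnot(inherits(cond, "condition_params"))
  response <- match.arg(response)
  p_o <- cond$guess$p_o
  Fd <- if (p_o < 1) {
    ddm_defective_cdf(t, cond$wiener, cond$var,
                      boundary = if (response == "correct") "upper" else "lower",
                      n_gh = n_gh, n_gl = n_gl)
  } else 0
  p_o * 0.5 * guess_cdf(t, cond$guess) + (1 - p_o) * Fd
}

#' Mixture RT density
#'
#' Defective RT density of the mixture for one response type, or the full RT
#' density pooled over both responses (`response = "either"`), including
#' across-trial variability of the diffusion component.  Useful for
#' inspecting the bimodal RT distributions that arise under heavy fast-guess
#' contamination.
#'
#' @inheritParams mixture_defective_cdf
#' @param response `"correct"`, `"error"`, or `"either"`.
#' @return Vector of density values.
#' @export
mixture_density <- function(t, cond, response = c("either", "correct", "error"),
                            n_gh = 20, n_gl = 10) {
  stopifnot(inherits(cond, "condition_params"))
  response <- match.arg(response)
  p_o <- cond$guess$p_o
  g <- guess_pdf(t, cond$guess)
  dd <- function(bnd) ddm_rt_density_var(t, cond$wiener, cond$var, bnd,
                                         n_gh = n_gh, n_gl = n_gl)
  if (response == "either") {
    fd <- if (p_o < 1) dd("upper") + dd("lower") else 0
    p_o * g + (1 - p_o) * fd
  } else {
    fd <- if (p_o < 1) dd(if (response == "correct") "upper" else "lower")
          else 0
    p_o * 0.5 * g + (1 - p_o) * fd
  }
}

#' Predicted accuracy of the mixture
#'
#' The mixture accuracy identity: `p_o * 0.5 + (1 - p_o) * P(correct)`,
#' where `P(correct)` is the variability-averaged upper-boundary absorption
#' probability of the diffusion component.
#'
#' @inheritParams mixture_defective_cdf
#' @return Probability of a correct response.
#' @export
mixture_accuracy <- function(cond, n_gh = 20, n_gl = 10) {
  stopifnot(inherits(cond, "condition_params"))
  p_o <- cond$guess$p_o
  pc <- if (p_o < 1) {
    ddm_defective_cdf(Inf, cond$wiener, cond$var, "upper",
                      n_gh = n_gh, n_gl = n_gl)
  } else 0.5
  p_o * 0.5 + (1 - p_o) * pc
}

#' Predicted inter-quantile bin probabilities
#'
#' Given the observed RT quantile edges for each response type, computes the
#' model-predicted probability mass in each inter-quantile bin: the mixture
#' defective CDF is evaluated at each edge and differenced, with the
#' response's total probability closing the final bin.  With 9 edges per
#' response this yields 10 bins per response (20 in all) whose masses sum to
#' the total probability 1.  A response type with no edges (the sparse-cell
#' fallback) is represented by a single bin carrying its full response
#' probability.
#'
#' @param edges_correct,edges_error strictly increasing RT edges (seconds)
#'   for the correct and error response, or `NULL` for the single-bin
#'   representation.
#' @param cond a [condition_params()] object.
#' @param floor lower clipping bound applied to each bin mass so that
#'   logarithms in the G-square statistic stay finite.
#' @param n_gh,n_gl quadrature orders.
#' @return A list with components `correct` and `error`, each a vector of
#'   bin probabilities.
#' @export
predicted_bin_probs <- function(edges_correct, edges_error, cond,
                                floor = 1e-10, n_gh = 20, n_gl = 10) {
  stopifnot(inherits(cond, "condition_params"))
  chk <- function(e, nm) {
    if (is.null(e) || length(e) == 0L) return(NULL)
    if (!is.numeric(e) || anyNA(e) || is.unsorted(e, strictly = TRUE))
      stop(sprintf("'%s' must be strictly increasing RT edges", nm),
           call. = FALSE)
    as.numeric(e)
  }
  edges_correct <- chk(edges_correct, "edges_correct")
  edges_error <- chk(edges_error, "edges_error")
  one <- function(edges, response) {
    Fv <- mixture_defective_cdf(c(edges, Inf), cond, response,
                                n_gh = n_gh, n_gl = n_gl)
    pmax(diff(c(0, Fv)), floor)
  }
  list(correct = one(edges_correct, "correct"),
       error = one(edges_error, "error"))
}
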
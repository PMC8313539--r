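# Gauss-Hermite / Gauss-Legendre node cache (raw rules; mapped per call)
.quad_cache <- new.env(parent = emptyenv())

gh_rule <- function(n) {
  key <- paste0("gh", n)
  if (is.null(.quad_cache[[key]]))
    .quad_cache[[key]] <- pracma::gaussHermite(n)
  .quad_cache[[key]]
}

gl_rule <- function(n) {
  key <- paste0("gl", n)
  if (is.null(.quad_cache[[key]]))
    .quad_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .quad_cache[[key]]
}

# Quadrature nodes/weights for the three across-trial integrals.
# Drift: Gauss-Hermite (normal weight); start and nondecision time:
# Gauss-Legendre mapped onto the uniform ranges.  Degenerate sources
# (zero variability) collapse to a single node so they cost nothing.
build_quad <- function(wiener, var, n_gh = 20, n_gl = 10) {
  if (var$eta > 0) {
    gh <- gh_rule(n_gh)
    vx <- wiener$v + sqrt(2) * var$eta * gh$x
    vw <- gh$w / sqrt(pi)
  } else {
    vx <- wiener$v; vw <- 1
  }
  if (var$sz > 0) {
    gl <- gl_rule(n_gl)
    zx <- wiener$z + (var$sz / 2) * gl$x
    zw <- gl$w / 2
  } else {
    zx <- wiener$z; zw <- 1
  }
  if (var$st > 0) {
    gl <- gl_rule(n_gl)
    tx <- var$ter + (var$st / 2) * gl$x
    tw <- gl$w / 2
  } else {
    tx <- var$ter; tw <- 1
  }
  list(vx = vx, vw = vw, zx = zx, zw = zw, tx = tx, tw = tw)
}

#' Probability of absorption at the upper boundary
#'
#' Closed-form absorption probability of the Wiener process without
#' across-trial variability:
#' \deqn{P(\mathrm{upper}) = \frac{1 - e^{-2 v z / s^2}}{1 - e^{-2 v a / s^2}}}
#' (and \eqn{z/a} in the zero-drift limit).
#'
#' @param params a [wiener_params()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @return Absorption probability in `(0, 1)`.
#' @examples
#' ddm_response_prob(wiener_params(a = 0.08, v = 0))  # 0.5
#' @export
ddm_response_prob <- function(params, boundary = c("upper", "lower")) {
  stopifnot(inherits(params, "wiener_params"))
  boundary <- match.arg(boundary)
  s2 <- params$s^2
  p_up <- if (abs(params$v) < 1e-12) {
    params$z / params$a
  } else {
    expm1(-2 * params$v * params$z / s2) /
      expm1(-2 * params$v * params$a / s2)
  }
  if (boundary == "upper") p_up else 1 - p_up
}

#' First-passage-time defective density of the Wiener process
#'
#' Density of the decision time at one boundary, without across-trial
#' variability and without nondecision time.  Evaluated by the standard
#' infinite-series representations, switching automatically between the
#' small-time and large-time expansions according to their truncation-error
#' bounds.  The two defective densities integrate to the corresponding
#' absorption probabilities, so their sum integrates to 1.
#'
#' @param t decision times in seconds; values `<= 0` return 0.
#' @param params a [wiener_params()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @return Vector of defective density values.
#' @export
ddm_fpt_density <- function(t, params, boundary = c("upper", "lower")) {
  stopifnot(inherits(params, "wiener_params"), is.numeric(t))
  boundary <- match.arg(boundary)
  wiener_pdf_cpp(as.numeric(t), params$a, params$z, params$v, params$s,
                 boundary == "upper")
}

#' Defective CDF of response time under across-trial variability
#'
#' Cumulative probability of a boundary-specific response by time `t`,
#' integrated over the across-trial distributions of drift rate (normal,
#' SD `eta`), starting point (uniform, range `sz`), and nondecision time
#' (uniform, mean `ter`, range `st`).  Integration uses Gauss-Hermite
#' quadrature over drift and Gauss-Legendre quadrature over the two uniform
#' ranges; the integrands are smooth so fixed-order rules are accurate and
#' deterministic.  `t = Inf` returns the variability-averaged absorption
#' probability (the asymptote of the defective distribution).
#'
#' @param t response times in seconds (decision plus nondecision);
#'   `t < ter - st/2` gives 0.
#' @param params a [wiener_params()] object.
#' @param var a [trial_variability()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @param n_gh Gauss-Hermite order for the drift integral.
#' @param n_gl Gauss-Legendre order for the starting-point and
#'   nondecision-time integrals.
#' @return Vector of cumulative probabilities.
#' @examples
#' p <- wiener_params(a = 0.106, v = 0.546)
#' v <- trial_variability(eta = 0.184, sz = 0.037, ter = 0.414, st = 0.129)
#' ddm_defective_cdf(c(0.5, 1, Inf), p, v, "upper")
#' @export
ddm_defective_cdf <- function(t, params, var, boundary = c("upper", "lower"),
                              n_gh = 20, n_gl = 10) {
  stopifnot(inherits(params, "wiener_params"),
            inherits(var, "trial_variability"), is.numeric(t))
  boundary <- match.arg(boundary)
  check_sz(params, var)
  q <- build_quad(params, var, n_gh, n_gl)
  t <- as.numeric(t)
  t[t < 1e-4 & t >= 0] <- 0        # sub-0.1-ms times carry no response mass
  wiener_cdf_var_cpp(t, params$a, params$s, boundary == "upper",
                     q$vx, q$vw, q$zx, q$zw, q$tx, q$tw)
}

# Defective RT density under across-trial variability (internal; used for
# mixture densities and bimodality diagnostics).  The uniform nondecision
# distribution convolves the decision-time density exactly into a difference
# of decision-time CDFs over the range, so only drift and starting point
# need quadrature.
ddm_rt_density_var <- function(t, params, var,
                               boundary = c("upper", "lower"),
                               n_gh = 20, n_gl = 10) {
  boundary <- match.arg(boundary)
  check_sz(params, var)
  q <- build_quad(params, var, n_gh, n_gl)
  upper <- boundary == "upper"
  t <- as.numeric(t)
  if (var$st > 0) {
    cdf_vz <- function(tt)
      wiener_cdf_var_cpp(pmax(tt, 0), params$a, params$s, upper,
                         q$vx, q$vw, q$zx, q$zw, 0, 1)
    tau <- t - var$ter
    (cdf_vz(tau + var$st / 2) - cdf_vz(tau - var$st / 2)) / var$st
  } else {
    wiener_pdf_var_cpp(t, params$a, params$s, upper,
                       q$vx, q$vw, q$zx, q$zw, var$ter, 1)
  }
}
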
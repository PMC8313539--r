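#' Wiener diffusion parameters for a single condition
#'
#' Bundles the core parameters of the two-boundary Wiener diffusion process:
#' boundary separation `a`, starting point `z`, mean drift rate `v`, and the
#' within-trial noise SD `s`.  Evidence units are arbitrary but must be
#' shared by `a`, `z`, `v` (per second) and `s` (per square-root second);
#' the package convention is `s = 0.1` (see [ddm_noise_scale()]).
#'
#' @param a boundary separation, `a > 0`.  The upper boundary sits at `a`
#'   (conventionally the correct response), the lower at 0.
#' @param v mean drift rate (evidence units per second); positive drift moves
#'   toward the upper boundary.
#' @param z starting point, `0 < z < a`.  Defaults to `a/2` (unbiased).
#' @param s within-trial noise SD.
#' @return An object of class `"wiener_params"`.
#' @examples
#' wiener_params(a = 0.106, v = 0.546)
#' @export
wiener_params <- function(a, v, z = a / 2, s = ddm_noise_scale()) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number", call. = FALSE)
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z <= 0 || z >= a)
    stop("'z' must satisfy 0 < z < a", call. = FALSE)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop("'v' must be a single finite number", call. = FALSE)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("'s' must be a single positive number", call. = FALSE)
  structure(list(a = a, z = z, v = v, s = s), class = "wiener_params")
}

#' Across-trial variability parameters
#'
#' Trial-to-trial variation of the diffusion process: drift rate varies
#' normally with SD `eta`, the starting point uniformly with range `sz`
#' (centered on `z`), and the nondecision time uniformly with mean `ter` and
#' range `st`.
#'
#' @param eta SD of the normal across-trial drift distribution (`eta >= 0`).
#' @param sz range of the uniform starting-point distribution (`sz >= 0`;
#'   must leave every start strictly inside the boundaries, i.e.
#'   `sz < 2 * min(z, a - z)`, checked when combined with a
#'   [wiener_params()] object).
#' @param ter mean nondecision time in seconds.
#' @param st range of the uniform nondecision-time distribution
#'   (`0 <= st <= 2 * ter`).
#' @return An object of class `"trial_variability"`.
#' @examples
#' trial_variability(eta = 0.184, sz = 0.037, ter = 0.414, st = 0.129)
#' @export
trial_variability <- function(eta = 0, sz = 0, ter = 0, st = 0) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    x
  }
  eta <- num1(eta, "eta"); sz <- num1(sz, "sz")
  ter <- num1(ter, "ter"); st <- num1(st, "st")
  if (eta < 0) stop("'eta' must be >= 0", call. = FALSE)
  if (sz < 0) stop("'sz' must be >= 0", call. = FALSE)
  if (ter < 0) stop("'ter' must be >= 0", call. = FALSE)
  if (st < 0 || st > 2 * ter)
    stop("'st' must satisfy 0 <= st <= 2 * ter", call. = FALSE)
  structure(list(eta = eta, sz = sz, ter = ter, st = st),
            class = "trial_variability")
}

# starting-point range must keep every start strictly inside (0, a)
check_sz <- function(wiener, var) {
  lim <- 2 * min(wiener$z, wiener$a - wiener$z)
  if (var$sz >= lim)
    stop(sprintf(
      "starting-point range sz = %g reaches a boundary (must be < %g)",
      var$sz, lim), call. = FALSE)
  invisible(TRUE)
}

#' Fast-guess component parameters
#'
#' On a guess trial the response is emitted without stimulus evaluation:
#' accuracy is exactly 50% and the latency is drawn from a normal
#' distribution with mean `mu_g` and SD `s_g`, truncated at zero (the
#' truncated mass is negligible for realistic values).
#'
#' @param p_o probability that a trial is a fast guess, in `[0, 1]`.
#' @param mu_g mean guess latency in seconds (`> 0`).
#' @param s_g SD of guess latencies in seconds (`> 0`).
#' @return An object of class `"guess_params"`.
#' @examples
#' guess_params(p_o = 0.735, mu_g = 0.262, s_g = 0.051)
#' @export
guess_params <- function(p_o, mu_g = 0.262, s_g = 0.051) {
  if (!is.numeric(p_o) || length(p_o) != 1L || !is.finite(p_o) ||
      p_o < 0 || p_o > 1)
    stop("'p_o' must be in [0, 1]", call. = FALSE)
  if (!is.numeric(mu_g) || length(mu_g) != 1L || mu_g <= 0)
    stop("'mu_g' must be positive", call. = FALSE)
  if (!is.numeric(s_g) || length(s_g) != 1L || s_g <= 0)
    stop("'s_g' must be positive", call. = FALSE)
  structure(list(p_o = p_o, mu_g = mu_g, s_g = s_g), class = "guess_params")
}

#' Full generative specification of one design cell
#'
#' @param wiener a [wiener_params()] object.
#' @param var a [trial_variability()] object.
#' @param guess a [guess_params()] object.
#' @return An object of class `"condition_params"`.
#' @export
condition_params <- function(wiener, var, guess) {
  stopifnot(inherits(wiener, "wiener_params"),
            inherits(var, "trial_variability"),
            inherits(guess, "guess_params"))
  check_sz(wiener, var)
  structure(list(wiener = wiener, var = var, guess = guess),
            class = "condition_params")
}

#' Constrained parameter set for the 5 x 5 experimental design
#'
#' Encodes the selective-influence structure of a 5 (speed-accuracy stress)
#' by 5 (stimulus contrast) design: boundary separation `a`, nondecision
#' time `ter`, and guess probability `p_o` vary only with the speed
#' condition (index 1 = extreme speed stress, 5 = extreme accuracy stress);
#' drift rate `v` varies only with contrast (index 1 = lowest contrast).
#' The across-trial variability parameters (`eta`, `sz`, `st`) and the guess
#' latency distribution (`mu_g`, `s_g`) are shared by all 25 cells.  The
#' starting point is `a/2` in every cell (unbiased responding).
#'
#' @param a,ter,p_o numeric vectors of length 5, indexed by speed condition.
#' @param v numeric vector of length 5, indexed by contrast condition.
#' @param eta,sz,st,mu_g,s_g scalars shared across cells.
#' @param s within-trial noise scale.
#' @return An object of class `"design_params"`.
#' @seealso [default_design()] for the canonical parameter values.
#' @export
design_params <- function(a, ter, p_o, v, eta, sz, st, mu_g, s_g,
                          s = ddm_noise_scale(), validate = TRUE) {
  vec5 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 5L || anyNA(x))
      stop(sprintf("'%s' must be a numeric vector of length 5", nm),
           call. = FALSE)
    unname(x)
  }
  a <- vec5(a, "a"); ter <- vec5(ter, "ter"); p_o <- vec5(p_o, "p_o")
  v <- vec5(v, "v")
  d <- structure(list(a = a, ter = ter, p_o = p_o, v = v, eta = eta,
                      sz = sz, st = st, mu_g = mu_g, s_g = s_g, s = s),
                 class = "design_params")
  # validate every cell through the component constructors (skipped on the
  # optimizer's hot path, where the transform guarantees validity)
  if (validate) for (sp in 1:5) for (co in 1:5) design_cell(d, sp, co)
  d
}

#' Extract the generative parameters of one design cell
#'
#' @param design a [design_params()] object.
#' @param speed speed-accuracy condition, 1 (extreme speed) to 5.
#' @param contrast contrast condition, 1 (lowest) to 5.
#' @return A [condition_params()] object.
#' @export
design_cell <- function(design, speed, contrast) {
  stopifnot(inherits(design, "design_params"),
            speed %in% 1:5, contrast %in% 1:5)
  condition_params(
    wiener = wiener_params(a = design$a[speed], v = design$v[contrast],
                           s = design$s),
    var = trial_variability(eta = design$eta, sz = design$sz,
                            ter = design$ter[speed], st = design$st),
    guess = guess_params(p_o = design$p_o[speed], mu_g = design$mu_g,
                         s_g = design$s_g))
}

#' Canonical design parameters
#'
#' The package's reference parameter set for a heavily speed-stressed 5 x 5
#' experiment: mean parameter values from mixture-model fits to an
#' orientation-discrimination experiment crossing five levels of
#' speed-accuracy stress with five levels of stimulus contrast (roughly 5000
#' trials per subject).  Under extreme speed stress about 74% of trials are
#' fast guesses; under accuracy stress guessing vanishes.  These values
#' drive the synthetic-data generator and serve as starting fixtures
#' throughout the package.
#'
#' @return A [design_params()] object.
#' @examples
#' d <- default_design()
#' d$p_o
#' @export
default_design <- function() {
  design_params(
    a    = c(0.063, 0.063, 0.072, 0.083, 0.106),
    ter  = c(0.356, 0.356, 0.382, 0.393, 0.414),
    p_o  = c(0.735, 0.201, 0, 0, 0),
    v    = c(0.108, 0.175, 0.283, 0.426, 0.546),
    eta  = 0.184, sz = 0.037, st = 0.129,
    mu_g = 0.262, s_g = 0.051)
}

#' @export
print.design_params <- function(x, ...) {
  cat("Constrained 5 x 5 design parameters\n")
  m <- rbind(a = x$a, ter = x$ter, p_o = x$p_o)
  colnames(m) <- paste0("speed", 1:5)
  print(round(m, 4))
  v <- rbind(v = x$v)
  colnames(v) <- paste0("contrast", 1:5)
  print(round(v, 4))
  cat(sprintf("shared: eta=%.3f sz=%.3f st=%.3f mu_g=%.3f s_g=%.3f s=%.2f\n",
              x$eta, x$sz, x$st, x$mu_g, x$s_g, x$s))
  invisible(x)
}
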
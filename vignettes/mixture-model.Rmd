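---
title: "Modeling fast-guess contamination in choice response times"
author: "ddmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling fast-guess contamination in choice response times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmix)
```

## The problem

When subjects in a two-choice task are pushed to respond extremely quickly,
some proportion of trials are *fast guesses*: responses initiated without
evaluating the stimulus, with chance accuracy and latencies mostly below
300 ms. Data contaminated this way show patterns no single-process
evidence-accumulation model can produce — bimodal RT distributions, chance
accuracy in the fast tail, and non-monotonic changes of RT variability and
skewness across speed-stress conditions. `ddmix` implements a two-process
account: each trial is, with probability $p_o$, a fast guess, and otherwise
a standard Wiener diffusion decision.

## The model

**Diffusion component.** Evidence accumulates from a starting point $z$
between absorbing boundaries $0$ and $a$ with drift $v$ and within-trial
noise $s$; the boundary reached determines the choice (upper = correct by
convention here, since every condition's generating drift is positive), and
the passage time plus a nondecision time gives the RT. Across trials, drift
varies normally with SD $\eta$, the starting point uniformly with range
$s_z$, and the nondecision time uniformly with mean $T_{er}$ and range
$s_t$. The noise scale is fixed at $s = 0.1$, the conventional choice that
makes boundary separations of 0.06–0.11 and drift rates of 0.1–0.55
ordinary magnitudes; it is a scaling constant, not an estimable parameter.
The starting point is fixed at $z = a/2$: the design's parameter count
(five each of $a$, $T_{er}$, $v$, $p_o$, plus $\eta$, $s_z$, $s_t$,
$\mu_g$, $s_g$) leaves no free bias parameter, and unbiased responding is
the natural assumption when the two responses are symmetric alternatives.

**Guess component.** Guess latencies are normal with mean $\mu_g$ and SD
$s_g$, truncated at zero and renormalized (RTs cannot be negative; at the
canonical values $\mu_g = 0.262$ s, $s_g = 0.051$ s, the truncated mass is
below $10^{-6}$, so truncation is a formality). Guess accuracy is exactly
0.5, independent of condition. Guess RTs live on the full RT scale rather
than being offset by the nondecision time: a mean guess latency of ~260 ms
is a plausible absolute latency for a stimulus-independent keypress, and
offsetting by $T_{er}$ would conflate two different motor pathways.
Whether the original fits in the literature truncated the guess normal at
zero is not stated anywhere we know of; the choice is immaterial at these
parameter values.

**Mixture.** For response $r$ at time $t$,
$$F_r(t) = p_o \cdot 0.5\,\Phi_g(t) + (1 - p_o)\,F^{\text{diff}}_r(t),$$
a defective CDF whose asymptote is the probability of response $r$. The
implied accuracy is $p_o/2 + (1 - p_o)\,P_{\text{diff}}(\text{correct})$.

**Design constraints (selective influence).** In the 5 (speed stress) × 5
(contrast) design, $a$, $T_{er}$ and $p_o$ vary only with speed stress;
$v$ varies only with contrast; $\eta$, $s_z$, $s_t$, $\mu_g$, $s_g$ are
shared by all 25 cells. That is 25 headline parameters for 475 data degrees
of freedom.

## Numerical evaluation

First-passage densities use the classical small-time and large-time series,
switching by truncation-error bound (tolerance $10^{-10}$ per evaluation);
neither series alone converges quickly across the 0.03–3 s range. The
defective CDF uses the large-time eigenfunction series with terms generated
by a multiplicative recurrence, so each extra term costs only
multiplications; below a normalized-time floor where the total absorbed
mass is provably below $10^{-20}$ the CDF returns exactly 0. RTs below
$10^{-4}$ s are treated as 0.

Across-trial variability is integrated by Gauss–Hermite quadrature over
drift (order 20) and Gauss–Legendre quadrature over starting point and
nondecision time (order 10 each): the integrands are smooth, so fixed-order
rules are accurate, deterministic, and cheap. One exception: the *density*
under nondecision-time variability is computed exactly as a difference of
CDFs over the uniform range (the box convolution has that closed form),
because node-based convolution of a peaked density produces small ripples
that can masquerade as spurious modes in bimodality diagnostics.

The Monte-Carlo oracle used in the test suite is an Euler–Maruyama path
simulation with a Brownian-bridge boundary-crossing correction, which
removes the $O(\sqrt{dt})$ crossing bias; at $dt = 5\times10^{-4}$ s its
residual bias is far below Monte-Carlo error at the sample sizes used. It
shares no code with the series evaluations, so agreement between the two is
a genuine two-route check.

## Fitting

The model is fit per subject by minimizing the quantile-based G-square
statistic $G^2 = 2\sum N\, p_i \ln(p_i/\pi_i)$ summed over the 25 cells.
Each response distribution is represented by its 0.1–0.9 deciles (type-7
linear interpolation), giving 10 bins per response whose observed
proportions are $0.1\,n_r/N$; model probabilities $\pi_i$ come from the
mixture defective CDF at the observed quantile edges, clipped below at
$10^{-10}$ so logarithms stay finite. When a response type has fewer than
11 observations in a cell, it is represented by a single bin (its response
probability only); published practice states a 15-observation rule only for
*plotting*, so the fitting threshold is this package's own choice — 11 is
the smallest count for which nine interior quantiles are all interpolated
from distinct order statistics.

Optimization is Nelder–Mead simplex on a transformed scale (log for
positive parameters; logit for $p_o$ and for the variability ranges as
fractions of their structural bounds $s_z < \min a$, $s_t < 2\min T_{er}$,
which makes every simplex point a valid model). The search is staged:
moment-based EZ-style heuristics give starting values (guess fraction from
sub-300-ms mass; $a$, $v$, $T_{er}$ from accuracy and RT moments of
slower-than-guess trials); a first pass freezes $\eta$, $s_z$, $s_t$ at
their starting values; the full vector is then released; and 3 random
restarts perturb the incumbent (SD 0.1 on the transformed scale), keeping
the best. The original fitting procedure's optimizer, restart policy, and
starting heuristics are unreported in the literature this design follows;
Nelder–Mead with restarts is the tradition for quantile-based diffusion
fitting.

Two modifications mirror practice for heavily contaminated data: estimated
$p_o < 0.1$ is set to exactly 0 and the model refit with it fixed (a full
refit, iterated to a fixed point, rather than post-hoc zeroing — the
re-released parameters absorb what the spurious guess mass was fitting);
and $a$, $T_{er}$ are tied across the two highest speed-stress conditions,
where guessing dominates and they are otherwise poorly identified. The
headline parameter count stays 25; the effective free count (23 with the
tie, minus zeroed $p_o$) is reported alongside. Degrees of freedom are
$475 - 25 = 450$ headline, with the critical value $\chi^2_{0.95}(450) =
500.5$; because G-square grows with the number of observations, fits up to
about twice the critical value still represent a good account of ~5000
observations, and the `goodness_of_fit()` grade reflects that.

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions this package targets: 20
subjects, a balanced 5 × 5 design at 200 trials per cell (5000 per
subject), guess probabilities falling from 0.735 under extreme speed stress
to 0 in the three slowest conditions, and the canonical parameter values of
`default_design()` throughout. Between-subject heterogeneity is a
multiplicative log-normal perturbation of each subject's parameters
(default SD 0.1 on the log scale): per-subject parameter dispersion is not
reported in the source literature, so this is a fixture choice sized to
produce realistic subject scatter, not an estimate. Zero guess
probabilities stay exactly zero under perturbation.

The generator reproduces the signatures that matter for the method: bimodal
speeded RT distributions, chance accuracy below 300 ms, the error−correct
RT sign flip across speed stress, and U-shaped CV and skewness profiles.
It deliberately does *not* reproduce anticipatory keypresses at a fixed
~31 ms latency that real speeded data can contain — those are outside both
the guess-normal and the diffusion process, so passing tests here say
nothing about a model's ability to capture them. Parameter-recovery results
on these data are likewise a best case: real data bring response omissions,
posture shifts, and parameter drift that the generator does not emulate.

## Problem sizes used in the checks

The test suite's simulation-versus-analytic comparisons use 150,000–200,000
trials per parameter set at $dt = 5\times10^{-4}$ s with three-binomial-SE
criteria; parameter recovery fits one synthetic subject at 200 trials per
cell; the self-consistency check evaluates the generating parameters on
2000 trials per cell against the 500.5 critical value; qualitative
benchmark checks use 1000 trials per cell. These sizes make Monte-Carlo
error small relative to every tolerance tested while keeping the whole
suite comfortably reproducible on a laptop.

## Limitations

- Drift is assumed positive toward the correct boundary in every cell, as
  in the design this package models; tasks with response bias need a free
  starting point, which the constrained design deliberately omits.
- The guess distribution is a symmetric normal; a right-skewed alternative
  (e.g. inverse Gaussian) fits similar data at the cost of a parameter and
  is not implemented.
- Time-varying drift, collapsing boundaries, and urgency signals are out of
  scope.
- The G-square landscape for 23–25 free parameters has local minima;
  restarts mitigate but cannot guarantee the global optimum. Fits report
  their optimizer trace so suspicious solutions can be re-run with a larger
  budget.

## A worked example

```{r example, eval = FALSE}
trials <- simulate_dataset(n_subjects = 1, n_trials_per_cell = 200,
                           seed = 11, between_subject_sd = 0)
fit <- fit_subject(trials, fit_config(seed = 1))
fit
goodness_of_fit(fit)
benchmark_table(trials)
chance_accuracy_test(trials)
```
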
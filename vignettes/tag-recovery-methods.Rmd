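---
title: "Estimating recovery from tagging: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating recovery from tagging: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagrecover)
```

## The problem

Capturing, handling and instrumenting a marine animal perturbs its
behaviour. Data recorded right after release mix this stress response with
the natural behaviour the tag was deployed to observe, so analysts either
discard an arbitrary initial stretch of data or risk contaminating their
baseline. `tagrecover` estimates *when* the animal returns to baseline, so
that exactly the affected stretch — no more, no less — can be trimmed.

Two behavioural channels are treated separately, because they recover at
different speeds:

* **fine-scale activity**, summarised from tri-axial accelerometry as
  VeDBA (vector norm of dynamic body acceleration, an energy-expenditure
  proxy), ODBA (its L1 variant) or jerk (norm of the differentiated raw
  acceleration, a rapid-movement proxy);
* **diving behaviour**, summarised from the depth trace as the pair
  (target depth, dive duration) per dive.

## Preprocessing

Depth records drift because pressure transducers are temperature
sensitive. `zero_offset_correct()` applies a two-pass moving-quantile
filter: a centred 20 s running median removes surface noise, then a
centred 30 min running 1% quantile of that output tracks the drifting
surface level; the corrected depth is the first output minus the second.
The 30 min window must exceed one diving cycle so that every window
contains surface samples; both windows and quantiles are configurable in
`species_config()`. The alternative of subtracting the second filter from
the *raw* trace (rather than from the median-filtered one) is available
via `method = "raw_minus_f2"`; the default follows the two-pass reading.
Windows are centred to avoid phase shifts, shrinking symmetrically at the
record edges; edge effects are confined to roughly half a window around
each dive boundary.

Dives are maximal runs of samples deeper than the 20 m surface threshold;
runs still open at the record boundaries are discarded because their
target depth is unknowable. Target depths are categorised
Shallow/Medium/Deep with left-open, right-closed edges (narwhal preset
160/360 m; bowhead preset 60/120 m).

The static (gravitational) component of acceleration is extracted per axis
with a 4th-order Butterworth low-pass at 0.1 Hz, run forward and backward
so the static series is not lagged relative to the raw one. The series is
padded by odd reflection (about ten filter time constants) before
filtering, which suppresses the start-up transients of the recursive
filter; residual edge error is below 10^-4 of the signal for records
longer than the pad. Jerk scales the first difference by the sampling
frequency so that its units are per second and values are comparable
across sampling rates. Metrics default to 1-minute block means for the
regression stage; hourly aggregation is available through
`aggregate_metric()`.

## Quantile-regression recovery

For a metric $Y$ with quantile level $\tau$, the model is

$$\log Y_\tau \mid \text{animal } i, \text{group } g, t
  \;=\; \beta_i + \alpha_g \, z, \qquad z = \frac{1}{t+1},$$

with $t$ in hours since release. Each animal has its own baseline offset
$\beta_i$; the tagging effect enters through the group slope $\alpha_g$
and decays hyperbolically: at release ($z = 1$) the $\tau$-quantile is
displaced by the factor $e^{\alpha_g}$, and the displacement vanishes as
$t \to \infty$. Working on quantiles rather than means makes the estimate
robust to the heavy-tailed, activity-dependent distributions of
accelerometer metrics, and lets the median ($\tau = 0.5$, typical
behaviour) and the upper tail ($\tau = 0.9$, vigorous behaviour) recover
at different rates. A categorical covariate (for example a handling-time
split) is parameterised directly as one free slope per group, which is the
identifiable form of a slope scaled by a covariate product.

Fitting minimises the pinball loss
$\sum_i \rho_\tau(\log y_i - \beta_{i} - \alpha_{g(i)} z_i)$,
$\rho_\tau(u) = u(\tau - 1\{u<0\})$, through the linear-programming
solvers of **quantreg** (Barrodale–Roberts simplex up to 20 000
observations, Frisch–Newton interior point above). Tests cross-check the
fit against exhaustive grid minimisation of the objective. Where the
optimum is a flat segment (possible with discrete data) the simplex
returns a vertex; the package's convention, matching its tests, is the
smallest minimizer — e.g. an intercept-only median fit of
$\{e^1, e^2, e^3, e^9\}$ returns 2.

**Return time.** The response is declared recovered at threshold
$\delta \in (0,1)$ when the displacement factor reaches $\delta$, i.e.
$e^{\alpha z} = \delta$, giving

$$t_R = \max\!\left(0,\; \frac{|\alpha|}{|\log \delta|} - 1\right).$$

$|\alpha|$ treats suppressed and elevated responses symmetrically. The
default $\delta = 0.25$ can be varied with `recovery_curve()`, which is
nondecreasing in $\delta$: demanding a displacement closer to one takes
longer. Infinite limits as $\delta \to 1$ are capped at the record length
on request.

**Uncertainty and contrasts.** Confidence intervals come from a cluster
bootstrap by animal (percentile method, 95%), the resampling unit that
respects within-animal serial dependence; a group with fewer than three
animals falls back to within-animal time blocks with a warning. A
resample that draws an animal $m$ times is fitted as a weighted problem
with integer weight $m$ — exactly equivalent to relabelled duplicates,
since $\rho_\tau(m u) = m \rho_\tau(u)$, but far cheaper. Slope equality
between groups, or between quantile levels within a group, is tested with
a Wald statistic whose standard error is the bootstrap SD of the slope
difference, referred to a Student t with (animals − groups) degrees of
freedom; the t reference keeps the test close to nominal size with the
small animal counts typical of tagging studies.

## Relative-entropy recovery of the dive profile

Each hour $[t, t+1)$ with at least one dive yields a probability vector
$P_t$ over the three depth categories, weighting each dive by its duration
(count weighting is available; duration weighting is the default because
an hour dominated by one long deep dive *is* a deep-diving hour). Hours
without dives are omitted rather than imputed: they carry no dive-profile
information.

The baseline $Q$ averages the $P_t$ of the *normal region* $t > t_N$,
an a-priori stretch assumed recovered ($t_N$: 40 h narwhal preset, 10 h
bowhead). Because tags detach at different times, the region is segmented
at the distinct record-end hours and segment $i$ gets weight
$w_i = n_i / \sum_j n_j$, $n_i$ being the number of animals still active
before drop point $i$ — late, sparsely observed hours are down-weighted
instead of either discarded or allowed to bias $Q$. Segments are
half-open $(t_{i-1}, t_i]$ so they partition the region; a segment left
without hours has its weight redistributed proportionally, with a
warning.

Divergence of hour $t$ from baseline is the Jensen–Shannon divergence
$J(P_t \| Q) = \tfrac12 K(P_t\|M) + \tfrac12 K(Q\|M)$, $M = (P_t+Q)/2$,
with base-2 logarithms so that $J \in [0,1]$; it is symmetric, always
finite, and $\sqrt J$ is a metric.

The *region of recovery* is the band of typical divergences inside the
normal region, estimated by leave-one-out cross-validation: for each hour
$t'$ in $(t_N, T]$ the reference is recomputed without it and
$J(P_{t'} \| Q_{-t'})$ recorded; the band is the closed empirical
2.5–97.5% interval (`quantile` type 7) of these values. $T$ (80 h
narwhal, 20 h bowhead presets) should be an early drop point: beyond it,
hourly distributions rest on few animals and would inflate the band.
Fewer than ten usable hours triggers a warning. For group comparisons the
band is built from the pooled leave-one-out values of all groups
(`combine_ror()`), under the assumption of a common normal-region
distribution; comparing the per-group bands to the unconditioned band is
the diagnostic for confounding by individual differences.

Hours are then labelled $+1$ inside the band (boundary inclusive) and
$-1$ outside, and the return time is estimated from the cumulative label
sum, which drifts down while the animal is perturbed and up afterwards.

### Breakpoint estimation

The kink of the cumulative sum is located by segmented regression
$y = a + b_1 x + b_2 (x - \psi)_+$ fitted by exhaustive search over
observed interior hours — exact at these series lengths, no iterative
linearisation needed — with ties resolved to the smallest $\psi$. A
straight-line series (no slope change to find) is flagged
"no breakpoint"; in standalone use a candidate kink must also cut the
straight-line SSR by at least half, a conservative screen against reading
curvature into noise.

Uncertainty comes from a bootstrap over disjoint `block_h`-hour blocks
(presets 5 h narwhal, 2 h bowhead; `block_width_rule()` implements the
$T^{1/3}$ rule of thumb). Two design points deserve emphasis, both fixed
from simulation experiments at design time:

1. **Blocks keep their hours.** A drawn block retains its original hour
   positions and the replicate is the drawn blocks sorted by those hours,
   duplicates adjacent — a cluster bootstrap over time blocks. Laying
   resampled blocks end-to-end in drawn order instead would scramble the
   perturbed-then-recovered structure and leave the replicate breakpoints
   unrelated to the transition.
2. **CUSUM anchoring and replicate validation.** With a perturbed phase
   of only two or three blocks, a global least-squares kink search is
   easily captured by stray out-of-band hours late in the series (the
   long arm dominates the SSR). The estimator therefore first locates the
   trough of the full-series cumulative sum — the CUSUM changepoint
   statistic for ±1 labels — and requires it to be interior and at least
   two label-hours deep; each replicate's segmented fit then refines the
   breakpoint within one block width of that anchor, and contributes only
   if the replicate itself has an interior trough of the same depth and a
   fall-then-rise shape ($b_1 < 0$, $b_1 + b_2 > 0$). Replicates failing
   these checks are counted and dropped; if they exceed half, or the
   full-series anchor fails, the result is "recovery not detected".
   Under a null label series (divergences typical throughout) essentially
   every replicate is rejected, while under a genuine 12 h step the drop
   rate stays below roughly a fifth.

The reported return time is the mean replicate breakpoint with a
percentile 95% interval. On noiseless step labels the estimator sits
within about one block width below the step — block loss can shorten the
visible perturbed phase but never lengthen it — a bias documented by the
tests and negligible next to the interval width on realistic data.

## Synthetic cohorts and what they do (not) show

`simulate_accel()` draws
$\log y = \beta_i + (a_g + b_g \varepsilon)z + \varepsilon$ with
$\varepsilon$ standard normal, so the true $\tau$-quantile satisfies the
regression model with slope $a_g + b_g\,\Phi^{-1}(\tau)$ — noise enters
both level and slope, making the tail genuinely recover at a different
rate from the median. Defaults: 10 animals per group, 100 h records,
minute observations, $a = -2.5$, $b = -1$, baseline offsets uniform on
[1, 2].

`simulate_dives()` draws Poisson(6) dives per hour whose category
composition switches (step, or exponential relaxation) from a perturbed,
shallow-dominated mixture (0.90, 0.08, 0.02) to a baseline mixture
(0.40, 0.35, 0.25) at a known hour (default 12); durations are lognormal
with category medians 120/420/720 s and sdlog 0.4, laid out sequentially
with random surface gaps so dives never overlap. These compositions and
duration laws are synthetic defaults chosen to be plausible for a
deep-diving odontocete — they are not measurements. Staggered drop-off
times exercise the reference-distribution weighting.

Both generators are pure functions of (scenario, seed) and leave the
caller's RNG state untouched.

Passing parameter-recovery tests on these cohorts shows the estimators
invert their own generating models at realistic sizes; it does not show
robustness to everything real records contain — tag slippage,
within-hour nonstationarity, activity-dependent noise spectra, or
surface behaviour misclassified as dives. The preprocessing tests cover
the standard failure modes (sensor drift, surface noise, edge
transients) but on stylised signals.

## Problem sizes and numerical conventions

Validation runs use the default cohort sizes above with 200–1000
bootstrap replicates depending on the statistic (200 for interval
coverage sweeps, 500 for reported intervals and Wald standard errors,
1000 for the breakpoint, matching its preset); null calibration of the
slope test uses 200 simulated cohorts of 6+6 animals at 36 h and 6
observations per hour. These sizes were chosen so each property is
measured on the scale at which the method is meant to operate while a
full validation sweep stays comfortably desk-sized.

Conventions: time origin at release, hour bins half-open $[h, h+1)$;
dive categories right-closed at the printed edges; probability vectors
validated to sum to one within $10^{-8}$; divergences clamped to
$[0, 1]$ against roundoff; quantiles of bootstrap samples and recovery
bands use `stats::quantile` type 7; all seeded routines restore the
caller's RNG state.

## Limitations

* The decay form $e^{\alpha/(t+1)}$ is monotone by construction; rebound
  or oscillatory recovery will be averaged through, not detected.
* The entropy stage needs a defensible normal region; if recovery is
  slower than $t_N$ the reference itself is contaminated (the breakpoint
  can still exceed $t_N$, but the band widens).
* Three depth categories are a coarse alphabet. A finer
  category-by-duration alphabet is straightforward but needs far more
  dives per hour to estimate $P_t$ stably.
* With very few animals, group differences are confounded with
  individual differences; the pairwise band diagnostic flags but cannot
  remove this.
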
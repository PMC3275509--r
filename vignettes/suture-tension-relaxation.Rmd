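---
title: "Modelling tension relaxation of knotted sutures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tension relaxation of knotted sutures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suturetension)
```

## The measurement and the model

When a surgical suture is knotted around soft tissue, the loop compresses
the enclosed tissue with a force that is anything but constant. An in-loop
force sensor sampling at 250 Hz shows that a freshly knotted non-elastic
monofilament loses a large share of its tension within the first hour, in a
stereotyped pattern with three phases:

1. **Rapid cutting phase (RCP)** — the first minute. The suture cuts into
   the tissue and tension drops from the peak at knotting, P0, to the
   1-minute value P1. The fractional loss (P0 − P1)/P0 is tissue specific
   (large in collagen-poor liver, small in collagen-rich skin).
2. **Constant declining phase (CDP)** — the following hour. Tension decays
   towards a plateau at an approximately constant *relative* rate: the gap
   above the plateau loses a fixed percentage each minute, interpreted as
   plastic deformation of the tissue.
3. **Plateau phase (PP)** — the residual tension Pplat, reflecting the
   remaining structural stability of the tissue.

The declining phase is modelled as

$$y(t) = a\,e^{-b\,t^{c}} + d,$$

with $t$ in minutes since the 1-minute transition, so that $a = P_1 -
P_\mathrm{plat}$ is the above-plateau amplitude at the window start, $b$ the
decay rate per minute, $c$ a time exponent, and $d = P_\mathrm{plat}$ the
plateau. With $c = 1$ (the default) the gap above the plateau shrinks by the
constant fraction $1 - e^{-b}$ every minute, which is what "a constant
per-minute decline" means; `decline_per_minute()` reports exactly this
quantity. Freeing $c$ (bounded to $[0.2, 3]$) generalises to stretched or
compressed exponential decay; the per-minute decline is then the
geometric-mean decline over the fit window.

The third phase is never detected as a changepoint: the plateau is *measured*
as the mean force over the trailing 60 s of the record, and the fitted $d$
is reported separately. The boundary "P2" between decline and plateau is
deliberately left undefined — the model needs no such point, since the
exponential approaches the plateau smoothly.

## Phase metrics and their conventions

`segment_phases()` computes, per suture:

* **P0** — maximum force over the first 5 s, at the full acquisition rate.
  Five seconds is long enough to catch the post-knot peak and short enough
  that even a 15%/min decline has removed well under 2% of the signal. On
  noisy traces the window maximum carries the usual positive max-of-n bias
  (about $3.2\sigma$ for 1250 samples); this mirrors how a peak would be
  read off a real record.
* **P1** — mean force over the fixed window 55–65 s. The rapid phase is
  *defined* as one minute, so P1 sits at a fixed time rather than at a
  detected gradient change; a ±5 s mean suppresses noise without touching
  the neighbouring phases.
* **Pplat** — mean force over the final 60 s, reported only when the trace
  spans the full configured record (3600 s by default).
* **Half-tension time** — first time the force falls to P0/2, linearly
  interpolated between the bracketing samples; first crossing wins. When
  the threshold is never reached, the record length (60 min) is reported as
  a *lower bound* with a censoring flag, matching the "> 60" convention of
  the reference table. Censored values are excluded from means and counted
  separately; no survival-style median is computed, because the analysis
  this package reproduces does not compute one.

P1, Pplat and the half-time are evaluated after block-mean decimation to 1 Hz
(`resample_trace()`): the relaxation varies on a minutes scale, so 250 Hz
adds cost, not information, while the 1 Hz block means average 250 samples
and reduce sensor noise by a factor of ~16. Decimation is the only smoothing
applied anywhere — no filter is assumed, since none is documented for the
original signal chain.

## The synthetic cohort generator

No raw sensor traces are publicly deposited, so the package ships a seeded
generator (`simulate_cohort()`) that emulates the measurement setting: 6
sutures per organ across liver, skin, stomach, muscle and small intestine,
60-minute records at 250 Hz, 0.077 gf (7.551e-4 N) quantization, and
additive Gaussian sensor noise (SD 0.02 N by default — a value chosen so
that single samples show visible noise while 1 Hz block means are clean,
consistent with the reported fit quality r > 0.95).

The noiseless mean curve is piecewise: an exponential approach from P0 to P1
with a 10 s time constant over the first minute (the cutting-through event
is treated as a single fast transient; 10 s makes it 99.75% complete at
60 s), then the relaxation model with $c = 1$ anchored at P1. Noise is added
per sample, then forces are quantized to sensor steps and clipped at 0.

Per-suture parameters are drawn from tissue profiles
(`builtin_profiles()`) that transcribe reported tissue characteristics.
Two parameterizations exist because the absolute rows (P0, P1, Pplat) and
the ratio rows (RCP %, plateau %) of that table are means of per-suture
quantities and are **not** mutually consistent when combined naively (liver:
0.9/2.6 = 34.6% yet the printed plateau ratio is 40 ± 18%). `mode =
"absolute"` draws the three tensions and derives the ratios; `mode =
"relative"` draws P0 and the two ratios and derives the tensions. Each check
uses the mode whose printed row it exercises.

Sampling is truncated-normal by re-draw: each parameter is re-drawn until it
lies in its valid range, and jointly constrained sets — (P0, P1, Pplat)
ordering in absolute mode, plateau ratio below 1 − loss in relative mode —
are re-drawn as a set (at most 100 attempts, then an error naming the
degenerate profile). Two consequences are worth knowing:

* Truncation at zero biases means upward; for the widest profiles (liver and
  stomach P0, SD ≈ 0.6 × mean) the bias is ≈ 11% of the SD. The tests
  therefore compare empirical means against the analytic truncated-normal
  mean, not the nominal mean.
* The sampler requires the 1-minute tension to exceed the plateau by at
  least 5% of the peak (`min_gap_frac`). Every suture in the emulated study
  shows a distinct declining phase — the reported model-measurement
  correlation exceeds 0.95 in every tissue — and an unconstrained
  independent draw of loss and ratio would instead produce occasional
  near-flat declining phases with arbitrarily small amplitude, a trace shape
  the measurement setting never exhibits.

Parameters are otherwise drawn independently: the source reports no
covariances, so none are modelled. This is a documented limitation — in
real data the first-minute loss is reportedly larger at higher peak
tensions, and collagen correlates within tissue with mechanical response.
Passing tests on this generator therefore demonstrate that the *pipeline*
recovers what the generator put in under realistic noise, quantization and
between-tissue structure; they cannot validate within-tissue covariance
structure, animal-level clustering (3 animals, repeated measures — ignored
here as in the original analysis), sensor drift, or the knot-tying
transient, none of which are modelled.

## Fitting: numerical choices

`fit_relaxation()` minimises squared residuals with bounded
Levenberg–Marquardt (via `minpack.lm::nlsLM`): $a \in (0, 2 P_0]$, $b \in
[10^{-4}, 10]$ per minute, $d \in [0,\ \max y]$, $c$ fixed at 1 unless
freed. Least squares matches the Gaussian noise model. Starting values come
from `initial_guess()`: the last-decile mean for $d_0$, the first-point gap
for $a_0$, a two-point log-gap slope for $b_0$ (floored at $10^{-3}$/min),
and $c_0 = 1$; a non-decaying trace yields a flagged flat-curve guess
rather than an error. Convergence is a relative cost change below
$10^{-10}$ or 500 iterations; non-convergence returns the best iterate
flagged `converged = FALSE`. Fit quality `r_fit` is the plain Pearson
correlation between fitted and measured force over the window.

The model-implied half-tension time (`half_time_from_fit()`) inverts the
fitted curve in closed form for $c = 1$ and by monotone root bracketing
(relative tolerance $10^{-6}$) otherwise, adding the 1-minute RCP offset.
If the fitted plateau already exceeds half-peak the result is censored; if
the threshold exceeds $a + d$ the crossing happened during the rapid phase
and the measured-trace crossing takes precedence.

## Cohort statistics

`summarize_by_tissue()` reports per-tissue mean ± sample SD (n − 1; a
single-suture tissue gets a missing SD, not zero), a Kruskal–Wallis omnibus
test per metric (tie-corrected H against $\chi^2_{k-1}$), and pairwise
Mann–Whitney tests **only** where the omnibus is significant at 0.05. No
multiple-testing correction is applied, because the analysis being
reproduced applies none — pairwise p-values should be read accordingly.
Mann–Whitney p-values are exact by enumeration for combined $n \le 12$
without ties, and normal-approximate with tie/continuity correction
otherwise; the U statistic counts pairs with $x > y$ (ties as ½), so
swapping samples maps $U \mapsto n_x n_y - U$.

Collagen correlations (`collagen_correlations()`) are Pearson coefficients
computed across all sutures pooled over tissues (n = 30 at the study
layout), matching the degrees of freedom implied by the published
correlations; tissue-mean correlations (n = 5) are emitted as a secondary
record. With the built-in profiles the pooled collagen/RCP-loss correlation
is negative and the collagen/plateau-ratio correlation positive in roughly
95% of seeded cohorts — the *sign* structure of the published findings. The
published magnitudes (r = −0.424, r = 0.392) are not reproducible without
the original per-suture data and are not claimed.

## Problem sizes used by the test suite

Single-trace checks run the full 250 Hz, 60-minute sensor (900,000 samples),
as does the 30-trace fit-quality cohort. Cohort-level distributional checks
run the generator at reduced acquisition rates (10 Hz for the 100-cohort
parameter-recovery study, 2 Hz for the 200-cohort correlation-sign study)
with the noise SD unchanged: the analysis path decimates to 1 Hz regardless,
so the reduced rates change only the effective noise after decimation, while
keeping the whole suite at a few minutes on one core. Parameter recovery at
these settings: median relative error of $b$ ≈ 0.1%, of $d$ ≈ 0.01%.

## Known limitations

* No within-tissue correlation structure between P0, RCP loss and plateau
  ratio (none is published); the pooled collagen correlations consequently
  arise purely from between-tissue structure.
* No animal-level random effects: sutures are treated as independent.
* No uncertainty quantification on fitted parameters.
* The trace format stores engineering units (newtons) only; raw 16-bit ADC
  streams are out of scope.
* Running sutures (as opposed to single knotted sutures) are not modelled.
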
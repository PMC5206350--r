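---
title: "Modelling and reconstructing phytomer development on grass tillers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and reconstructing phytomer development on grass tillers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytodev)
```

## The biological model

A vegetative grass tiller is a stack of phytomers — repeated units of leaf
blade, leaf sheath, node and internode — that elongate one after another in
a tightly coordinated sequence. `phytodev` encodes that coordination as a
small set of quantitative rules and provides both a forward simulator (a
virtual greenhouse experiment) and the analysis pipeline that reconstructs
the rules from the kind of data such an experiment yields.

The development of a single phytomer is described on a normalized scale:
its *fraction of final length*, `f_L = L_a / L_p`, the actual length over
the (predicted) final length. Three rules govern the dynamics:

1. **The complete time course.** `f_L` follows a two-parameter logistic in
   days after tip emergence, `f(x) = 1 / {1 + exp[(x0 - x)/b]}` with
   defaults `x0 = 1.82` d and `b = 1.81` d. At tip emergence (`x = 0`) the
   phytomer has already reached ~26–27 % of its final length, hidden inside
   the whorl of enclosing sheaths; growth effectively ceases at 99 % about
   10–11 d later.
2. **Within-phytomer partition.** Elongation is all blade until 50 % of
   final length; the blade finishes at its final 66 % share while the
   phytomer advances to 75 %; the sheath completes its 14 % share at 80 %;
   the remaining 20 % is internode. `partition_components()` implements
   this piecewise-linear, exactly conserving rule. The package also carries
   the empirical regression curves for the same relationships
   (`coordination_rules()`): a blade sigmoid (0.73, 0.37, 0.17), a sheath
   sigmoid (0.46, 0.94, 0.13) and an internode line `0.04 x - 0.0063`.
   The two representations are deliberately *not* reconciled: the fitted
   asymptotes do not conserve length (0.73 + 0.46 > 1), so the generator
   uses the threshold rule and the curves serve as reference regressions.
3. **Between phytomers.** Rank `r` starts one phyllochron (default 2.3 d,
   with per-treatment values 2.4/2.4/2.1/2.4 d) after rank `r - 1`. The
   empirical between-phytomer regression (1.34, 0.91, 0.24) is kept for
   evaluation on `[0, 1]` only; its tail is not consistent with a pure
   phyllochron offset (it implies a larger developmental lag near
   completion), which is a known property of the offset model documented
   here rather than hidden.

Thermal time is linear: at a constant 25 °C, 37 d of growth are
`thermal_time(37, 25, 0) = 925` degree days; above a base of 10.8 °C the
13-d elongation span corresponds to 185 degree days and the quasi-linear
phase (6 d) to 85.

## What the simulator emulates

`generate_experiment()` forward-simulates a 2 × 2 nitrogen × VPD factorial
(two chambers per cell, eight tillers per chamber, 64 tillers) and applies
two virtual instruments:

* **Daily ruler observations** (days 24–37): the distance from each
  emerged phytomer tip to the next older *visible* ligule, rounded half-up
  to 0.5 mm. Visibility and emergence come from an explicit 1-D height
  model: nodes stack on internodes, a phytomer's tip is its insertion node
  plus its own length, and a ligule becomes visible once its sheath has
  ceased elongating. A tip emerges when it clears the tallest enclosing
  sheath top. Because the reference ligule and the growing tip share the
  internodes below them, day-to-day changes of the measured distance equal
  the phytomer's true elongation — the property the field protocol relies
  on.
* **Destructive dissection** (day 37): blade, sheath and internode lengths
  per phytomer, rounded to 0.5 mm, with phytomers at or below 4 mm
  discarded (the shoot apex region).

Final lengths follow a rank profile — a 100 mm plateau up to rank 8, then
a linear decline of 4 % of the plateau per rank (so rank 13 is 80 % of
rank 8) — times lognormal noise with a total coefficient of variation of
0.10. That noise is split into a shared tiller-level size factor (80 % of
the variance) and a small per-phytomer residual: the normalization by
predicted final length exists precisely because plant-to-plant size
heterogeneity is large in wild grasses, while the within-tiller rank
profile is smooth. A pure per-phytomer interpretation would make the
per-tiller final-length extrapolation far noisier than real dissection
tables are. Initiation times carry Gaussian jitter (sd 0.2 d).

Two geometric calibrations deserve explanation because the narrative
component shares alone cannot produce them:

* **Whorl height** (`whorl_fraction`, default 0.236 of the enclosing
  phytomer's final length). If the enclosing whorl were only as tall as
  the enclosing phytomer's own 14 % sheath share, tips would emerge at
  ~14–16 % of final length instead of the observed ~26 %. The fitted
  sheath regression in fact reaches ~27 % of phytomer length near full
  expansion, so the pseudostem is modelled with its own height parameter,
  calibrated so that zero-noise emergence over the observed ranks spans
  f ≈ 0.25–0.27 and averages the time course's `f(0) = 0.2675`. The
  dissected sheath share (14 %) and the whorl height (23.6 %) are thus two
  different measurements of sheath-related geometry, mirroring the
  conflicting representations in real data.
* **Emergence clock offset** (`emergence_offset`, default −5 d: rank `r`
  emerges at `-5 + r × phyllochron`). This places a monitored rank's full
  visible phase — emergence to cessation — inside the day 24–37 window for
  every treatment phyllochron: rank 12 for the 2.4-d treatments, rank 14
  for the 2.1-d treatment (hence the default `monitored_ranks = 12:14`).

What the generator does *not* emulate: tillering dynamics (tiller counts
enter as per-treatment constants), 3-D geometry, any mechanistic water or
nitrogen physiology (treatments act only through parameter overrides), and
treatment differences in the time-course curve itself — the curve is shared
across treatments, which is the central invariance the analysis is meant
to recover. Passing tests therefore show that the pipeline recovers the
rules *of this generative model* under realistic censoring, rounding and
noise; they cannot certify behaviour on real data with, say, curvature in
the rank profile or non-logistic elongation.

## The reconstruction pipeline

`reconstruct_experiment()` chains the stages; each is exported separately.

* **Emergence** (`estimate_emergence()`): a tip usually emerges between
  daily visits, so the first recorded distance divided by the elongation
  rate just after (the first one-day increment) estimates the lag, which
  is subtracted from the first observation day. Events whose implied lag
  exceeds `max_lag = 1.5` d are flagged unreliable — phytomers that
  emerged long before observation began cannot be dated by a linear
  extrapolation through the decelerating part of the curve.
* **Phyllochron** (`compute_phyllochron()`): mean spacing of successive
  reliable emergences within ranks 7–16, normalized by rank gaps.
* **Cessation** (`detect_full_expansion()`): the first day opening `k = 2`
  consecutive daily intervals in which the recorded distance changes by
  less than one ruler step (i.e. not at all on the 0.5 mm grid). On a
  rounded ruler this detects cessation ~1–2 d *after* the true 99 %
  crossing because the elongation tail creeps one step every other day —
  which is also why an observed visible growth duration of ~11 d is
  consistent with a curve whose 99 % point lies at 10.1 d.
* **Final lengths** (`predict_final_length()`): a per-tiller least-squares
  line of mature length vs rank (ranks ≥ 8), extrapolated to the tiller's
  immature ranks. Mature phytomers keep their measured length, so their
  fraction is exactly 1.
* **Visible time course** (`build_visible_timecourse()`): for phytomers
  covered from emergence to cessation, daily actual lengths are rebuilt
  backwards from the measured final length by subtracting the daily
  increments; increments spanning a change of reference ligule or a data
  gap are interpolated from neighbouring rates (each interpolation is
  logged).
* **Initial phase** (`assign_invisible_ages()`): per tiller, one immature
  phytomer at 60–80 % of its final length is anchored on the
  treatment-specific visible-phase fit via the closed-form inverse of the
  logistic; younger phytomers are dated by subtracting one phyllochron per
  rank. Among several window candidates the one closest to the window
  midpoint is used: noisy final-length predictions push phytomers across
  the window edges from both sides, and edge candidates are exactly the
  suspect ones. (With clean data this coincides with taking the oldest
  candidate.) Tillers without a candidate, or in a treatment without a
  visible-phase fit, are skipped with a warning.
* **Coordination tables** (`build_coordination_tables()`): component
  fractions vs phytomer fraction (within), and fractions of adjacent
  phytomer pairs ordered older → younger (between).

Curve fitting (`fit_sigmoid2()`, `fit_sigmoid3()`, `fit_linear()`) uses
Levenberg–Marquardt least squares with positivity enforced by
log-parameterizing the scale (and amplitude), starting values taken from
the half-range crossing and the central-quartile slope, a relative
convergence tolerance of 1e-10 and at most 500 iterations, and no point
weighting. Fit objects carry `R²`, the residual standard error
`sqrt(SSR/(n − p))` and the SSR, and have `tidy()`/`glance()` methods.

## Numerical choices and degenerate inputs

* Rounding of measurements is half-up (`12.25 → 12.5`) on the resolution
  grid; reported percentages round half-up to integers, which is how a
  −12.5 % phyllochron effect prints as −13 %.
* A `measurement_resolution` of 0 means an exact ruler — the configuration
  used for noise-free validation together with zero length and timing
  noise.
* Emergence times in the simulator are found by bracketing the
  tip-vs-whorl crossing on a 0.05-d grid and refining linearly; the
  *last* upcrossing is used because the logistic's infinite lower tail
  gives every phytomer an infinitesimal positive length long before the
  whorl exists.
* Degenerate analysis inputs fail loudly: fewer than three mature
  phytomers for extrapolation, a single emergence event for a phyllochron,
  constant ordinates for a sigmoid fit, a non-positive predicted final
  length. Validation of the CSV tables treats missing required columns and
  negative lengths as errors, unknown columns and off-grid distances as
  warnings.

## Known limitations

* With daily sampling, the age origin (tip emergence) can only be
  estimated to ~0.01–0.1 d: the linear lag rule inherits the curve's
  curvature over the sub-day interval, and no amount of later data can
  remove this, because shifting all ages and the midpoint jointly leaves
  the fit unchanged. Noise-free round trips therefore recover `x0` and `b`
  to about 0.003 and 0.01 d respectively, not to machine-like precision.
* The smallest reconstructable fraction is bounded by the 4 mm dissection
  rule (~0.05–0.06 at the youngest ranks' final lengths), so the initial
  phase starts around f ≈ 0.1–0.2 here.
* The between-phytomer regression and the phyllochron-offset clock
  disagree near completion; the generator follows the clock.

## Problem sizes

The test suite exercises small designs (1–2 tillers per chamber, a single
chamber per cell) for unit and property checks, and the full 64-tiller
default experiment for end-to-end parameter recovery; the latter is the
size used by `scripts/acceptance.R` and runs in well under a minute.
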
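---
title: "Monitoring and predicting the lye treatment of green table olives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring and predicting the lye treatment of green table olives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olivecook)
```

## The problem

Sevillian-style green table olives are debittered by immersion in dilute
NaOH ("lye treatment" or cooking). The lye penetrates from the skin inward,
hydrolysing the bitter glucoside; the cook must be stopped when penetration
reaches roughly two-thirds to three-quarters of the flesh. Traditionally a
factory expert (the *maestro cocedero*) cuts olives open, sprays
phenolphthalein on the cut face — NaOH-affected flesh turns pink/fuchsia,
untreated flesh stays yellow-green — and judges the stained fraction by eye.

`olivecook` replaces both halves of this judgement with measurements:

1. **imaging** — quantify the stained fraction of each cut face from a
   scanner image of olive halves arranged on an alveolar tray;
2. **prediction** — interpolate the resulting cooking curve
   (time vs. treated percentage) and invert it to forecast *when* the target
   penetration will be reached, so tank sampling can be scheduled and the
   cook stopped on time.

## The imaging pipeline

Olive halves sit in a rows x columns tray (4 x 8 and 4 x 6 in practice) on a
dark support. `measure_grid()` composes three steps:

* **Background segmentation** (`segment_background()`). The dark support has
  near-zero blue intensity, while both stained (fuchsia) and unstained
  (yellow-green) flesh carry appreciable blue, so a threshold on the blue
  channel separates foreground from background. The threshold is taken from
  Otsu's method on the blue histogram by default (robust to overall
  illumination level) or can be fixed. A morphological closing (disc radius
  2 px by default) fills small holes, and components below
  `min_olive_area_px` (200 px) are discarded as debris. A blue support is
  also supported (`background_colour = "blue"`): there background pixels are
  strongly blue *and* red-poor, since fuchsia flesh is itself blue-rich.
* **Grid assignment** (`detect_olives()`). Connected components are assigned
  to the cell of a uniform tiling that contains their centroid, 0-based
  row-major, row 0 at the top. The tray fixes positions physically, so
  centroid-in-cell is unambiguous; if two components fall in one cell the
  larger wins, and components beyond the tray capacity are dropped by area
  rank with a warning.
* **Treated classification** (`classify_treated()`). Phenolphthalein pink
  has strong red and suppressed green, untreated flesh has green close to or
  above red. The default rule is a channel difference: a foreground pixel is
  treated iff `R - G >= 40` and `R >= 100`. These thresholds are deliberate
  package defaults, calibrated on the synthetic fixtures and fully
  configurable; an alternative hue-band mode classifies by hue angle
  (default 280–350 degrees). Saturated white pixels (all channels >= 250),
  typically specular highlights on drying flesh, are conservatively counted
  as untreated; this too is configurable.

Two summary percentages are reported, since both conventions are defensible:
`pooled_pct = 100 * sum(treated px) / sum(total px)` — the area fraction of
the whole sample, the headline value, being the natural estimate of the
surface affected — and `mean_pct`, the unweighted mean of per-olive
percentages. No attempt is made to mask pit remnants: the whole cut face
counts. `average_replicates()` averages repeated scans of the same time
point (five repetitions per time point is typical practice).

## The anchored interpolation predictor

The cooking curve — treated percentage vs. hours since NaOH addition — is
sigmoid: a slow initial phase while the skin resists penetration, a fast
middle phase, and saturation. Two boundary points are known *a priori*: at
`t = 0` the percentage is 0, and if the cook were (wrongly) extended far
past its optimum the flesh would be fully treated — 100% at `t_end_h`, 24 h
by default, the maximum recommended process duration. `olivecook` appends
both anchors as ordinary knots before fitting; this is the simplest
mechanism that makes an interpolant defined on the whole of `[0, t_end_h]`
and guarantees that every target percentage up to 100 is crossed, even with
very few observations. Tightening `t_end_h` when tank-specific knowledge
exists is supported and sharpens early predictions.

Three interpolants are available via `build_interpolant()`:

* **linear** — piecewise linear (`stats::approxfun`);
* **pchip** — Fritsch–Carlson shape-preserving cubic Hermite
  (`pracma::pchip`): node slopes are weighted harmonic means of adjacent
  secants, zero at local extrema, so monotone data yield a monotone curve
  and the target crossing is unique;
* **makima** — modified Akima cubic Hermite, implemented in this package
  (`makima()`): node slopes weight adjacent secants by
  `w1 = |d[i+1] - d[i]| + |d[i+1] + d[i]|/2` and
  `w2 = |d[i-1] - d[i-2]| + |d[i-1] + d[i-2]|/2`, with the standard
  two-virtual-point extension of the secant sequence at each end and the
  `w1 + w2 = 0` tie resolved to the mean of the adjacent secants. This
  damps the ringing of classic Akima near flat regions but does not
  guarantee monotonicity. The implementation is verified in the test suite
  against values frozen from an independent reference implementation.

With fewer than three knots the cubic methods reduce to the linear
interpolant (a cubic Hermite through two points with secant slopes *is* the
line), so anchors-only queries are well defined.

`predict_completion()` inverts the interpolant: the estimate is the
*earliest* `t` with `pct(t) >= target_pct`, located by scanning a uniform
grid (`grid_step_h = 0.01` h) and refining the bracketing interval by
bisection to `1e-6` h. Grid-scan-plus-bisection was chosen over analytic
cubic-root solving because it is method-agnostic and directly testable
against a brute-force oracle (the suite checks agreement within `1e-3` h on
random monotone curves at 100 x finer resolution). Taking the first
crossing matters for makima, which can overshoot and cross a target more
than once: the earliest crossing is the safe stop time, and underestimation
errs on the side of alerting the operator early. Predictions are refused
until `min_samples` observations exist (default 4, the point at which
estimates become meaningful in practice); a curve with *no* observations is
the degenerate anchors-only query and is allowed.

### Error conventions

`relative_error()` is signed: `100 * (t_est - t_real) / t_real`, positive
for overestimates. `running_prediction_table()` tabulates predictions and
errors for every sample prefix `n = min_samples, ..., N`; by default
estimated times are rounded to 2 decimals *before* the error quotient is
formed, so a printed table reproduces its own arithmetic exactly.
`average_absolute_error()` — the mean of absolute errors across trials — is
the figure of merit for comparing methods; on the bundled factory benchmark
(`olive_trials("factory")`, twelve production cooks) it is 21.18% for
linear, 6.95% for PCHIP and 5.33% for makima, which is why the cubic
methods are the recommended estimators and linear is kept only as a
baseline.

### The default target

`prediction_config()` targets 66.7% by default: the classical rule stops
the lye when it has penetrated about two-thirds of the flesh. The target is
the first parameter a deployment should revisit — olive variety and
ripeness move the expert's preferred end point (75% and 85% are also used).

## The synthetic-data generator

No public imagery or curve data exist for this process, so the `synthetic`
module is first-class, tested code that defines the study conditions for
everything else.

* `render_grid()` draws one ellipse per tray cell on the support colour.
  The treated region is a concentric outer **annulus**: penetration
  advances from the skin inward, so the annulus of normalised elliptical
  radius `sqrt(1 - f) < r <= 1` has continuous area fraction exactly `f`,
  making the ground truth analytically controllable. Default colours —
  flesh (150, 160, 60), stain (200, 60, 120), background (5, 5, 5) — match
  the qualitative contrast of real phenolphthalein scans. Per-olive size
  jitter (±8%) and additive Gaussian channel noise are available; rendering
  is deterministic under the spec's seed. Real stain fronts are ragged, not
  concentric, and real scans have shadows, glare and pit remnants; passing
  the recovery tests therefore demonstrates correctness of the measurement
  arithmetic and robustness to channel noise, not photometric performance
  on factory scans, for which the thresholds exist as tuning points.
* `sample_curve()` samples a logistic
  `saturation / (1 + exp(-rate * (t - midpoint)))`, shifted so the curve
  starts at 0% and clipped to `[0, 100]`, at a fixed cadence with truncated
  Gaussian observation noise. A logistic is the simplest curve with the
  observed three phases; an optional dead time `lag_h` (default 0) delays
  onset. Defaults mirror the instrumented laboratory cook: saturation
  84.3% (a typical expert end-point percentage), 8 h duration, hourly
  samples, 1 point of observation noise, midpoint 4.5 h, rate 1.1 per hour.

## Benchmark problem sizes

The package's own benchmark (in `scripts/acceptance.R` and the test suite)
draws 100 curves with midpoint uniform in [3.5, 5.5] h and rate uniform in
[0.8, 1.5] per hour, predicts the two-thirds crossing from the first six
hourly samples plus anchors, and takes the median absolute relative error
per method against the noiseless curve's true crossing; typical values are
under 2% for both PCHIP and makima. Imaging recovery is exercised on
rendered 4 x 6 (720 x 480 px) and 4 x 8 (960 x 480 px) grids — large enough
for sub-percent discretisation error of the annulus areas, small enough
that the whole suite runs in seconds.

## Known limitations

* Segmentation/classification thresholds are calibrated on synthetic
  imagery; factory deployments should validate them on their own scanner
  and lighting, via the audit outputs of `cmd_measure()`.
* The predictor uses time as the only covariate; tank temperature and NaOH
  concentration, though routinely monitored, are not modelled.
* Makima predictions can be non-monotone between sparse samples; the
  first-crossing rule bounds the consequence but cannot remove it.
* The annulus stain model and logistic curve family are idealisations; see
  the generator section for what tests on them do and do not show.
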
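# olivecook

Vision-based monitoring of the lye treatment ("cooking") of Sevillian-style
green table olives, and prediction of the optimal moment to stop it.

Green olives are debittered by immersion in dilute NaOH. The lye penetrates
from the skin inward and the cook must stop when penetration reaches about
two-thirds to three-quarters of the flesh; overshooting ruins texture,
undershooting leaves the fruit bitter. The traditional control is visual: an
expert cuts olives open, sprays phenolphthalein (NaOH-affected flesh turns
fuchsia, untreated flesh stays yellow-green) and judges the stained fraction
by eye. `olivecook` measures it instead, and forecasts the finishing time.

**Imaging.** Olive halves are scanned in a rows x columns alveolar tray on a
dark support. `measure_grid()` segments olives from the background by
thresholding the blue channel (Otsu by default), assigns each connected
component to its tray cell by centroid, classifies foreground pixels as
NaOH-treated with a red/green rule (treated iff `R − G ≥ 40` and `R ≥ 100`,
configurable; phenolphthalein pink has strong red and suppressed green), and
reports the lye-treatment percentage `L.T. = 100 · treated px / total px`
per olive and pooled over the grid.

**Prediction.** The cooking curve (time vs. treated percentage) is
interpolated with two known anchors appended as knots — `(0 h, 0 %)` at the
start and `(24 h, 100 %)` at the hypothetical full-treatment end — using
linear, PCHIP (Fritsch–Carlson shape-preserving cubic Hermite) or modified
Akima (makima) interpolation. `predict_completion()` inverts the anchored
interpolant: the estimated finishing time is the first `t` with
`pct(t) ≥ target`, and `relative_error()` benchmarks it against the
expert-decided real end time as `100 · (t_est − t_real) / t_real`.

**Synthetic data.** No public factory data exist, so the package ships a
seeded generator: `render_grid()` draws olive grids with exactly controlled
per-olive treated fractions (the stain is an outer annulus — penetration
advances from the skin inward), and `sample_curve()` samples logistic
cooking curves with a slow initial phase. Every pipeline claim is tested
against this ground truth.

## Worked example

Measure a synthetic 4 x 6 grid rendered at 55 % treated with channel noise:

```r
library(olivecook)
spec <- synthetic_grid_spec(layout = grid_layout(4, 6),
                            per_olive_treated_fraction = 0.55,
                            noise_sigma = 8, seed = 42)
g <- render_grid(spec)
measure_grid(g$image, grid_layout(4, 6))
#> <grid_measurement: 24 olives, pooled 55.0%, mean 55.0%>
```

All 24 olives are found and the pooled percentage recovers the rendered
ground truth (55.03 %) to a tenth of a point. Now sample a cooking curve and
watch the prediction converge as hourly samples accumulate:

```r
cspec <- synthetic_curve_spec(seed = 42)      # logistic, saturation 84.3 %
cv <- sample_curve(cspec)                     # 8 hourly observations
t_real <- true_crossing_time(cspec, 66.7)     # 5.750 h, the 2/3 point
running_prediction_table(cv, prediction_config(target_pct = 66.7), t_real)
#>   n_samples t_linear t_pchip t_makima   t_real    e_linear    e_pchip   e_makima
#> 1         4    14.36    9.92     8.26 5.750387 149.7223056 72.5101164 43.6424961
#> 2         5    10.46    7.54     6.10 5.750387  81.9007880 31.1216006  6.0798095
#> 3         6     5.80    5.68     5.72 5.750387   0.8627697 -1.2240463 -0.5284410
#> 4         7     5.80    5.76     5.76 5.750387   0.8627697  0.1671644  0.1671644
#> 5         8     5.80    5.76     5.76 5.750387   0.8627697  0.1671644  0.1671644
```

By the sixth sample every method is within 1.3 % of the true finishing
time; the signed errors are positive for overestimates. The bundled
benchmark of twelve production-tank cooks shows why the cubic methods are
preferred:

```r
cmd_report(olive_trials("factory"))$mean_abs
#>  e_linear   e_pchip  e_makima
#> 21.180833  6.945833  5.327500
```

i.e. mean absolute errors of 21.18 % (linear), 6.95 % (PCHIP) and 5.33 %
(makima) against the expert's end times.

A command-line interface with `measure`, `predict`, `simulate` and `report`
subcommands is installed at
`system.file("cli", "olivecook", package = "olivecook")`.

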
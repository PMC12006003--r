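# photofade

Quantifying how photobleaching corrupts fluorescence-based morphometry.

Epifluorescence micrographs fade under the excitation beam: every second of
illumination irreversibly destroys part of the fluorophore population. For
anyone quantifying immunostained tissue — mean staining intensity, counts of
NeuN-positive neurons with a discernible nucleus, Iba1-labelled microglial
area coverage, or single-cell fractal morphometry — the image is therefore a
moving target, and readouts taken after different cumulative illumination
times are not comparable. `photofade` simulates this process end to end and
measures how much information each readout class loses as illumination
accumulates.

The package is organised as an analysis workflow: all computation lives in
the package functions (`R/`), thin narrative drivers under `analysis/`
reproduce the study tables into `results/`, and `scripts/acceptance.R`
recomputes the headline numbers from scratch.

## Model

A scene is a ground-truth field of synthetic cells: NeuN-like neurons (an
elliptical soma enclosing a brighter, flat nucleus) or Iba1-like microglia
(a soma disk with a recursively branched process tree, 2–5 cells per field,
tube-like structures rendered with a chord-profile intensity falloff).
Pixel signal fades bi-exponentially with cumulative illumination time *t*:

    d(t) = f_fast · exp(−k_fast t) + (1 − f_fast) · exp(−k_slow t)
    E[I(x,t)] = B + (D + S(x)) · d(t)

where `B` is the non-bleaching background (mount autofluorescence, camera
offset), `D` a spatially uniform *bleachable* diffuse staining level, and
`S(x)` the cell amplitude map. Poisson shot noise, Gaussian read noise and
8-bit quantisation complete the camera model. Kinetics are calibrated per
dye to the published whole-frame loss schedules (45% total loss for the
photostable A488-Plus-like dye, 65% for the A546-like dye); scene
heterogeneity (nucleus and soma brightness distributions) is calibrated to
the published detectable-neuron and area-coverage losses.

Four readout families are then measured on the simulated series:

1. **Whole-frame mean intensity** and its relative loss curve, with the
   descriptive second-degree polynomial and linear fits.
2. **Neuron census**: a nucleus is "discernible" when its mean exceeds the
   initial-frame background by 3 SD and at least half its pixels do.
3. **Area coverage**: threshold segmentation with a cutoff fixed from the
   initial frame's background statistics (mode + 3 robust SD).
4. **Single-cell morphometry**: paired binary profiles at 0 s and at the
   dye's endpoint of detection (900 s A488-like, 120 s A546-like), with
   box-counting fractal dimension, lacunarity, convex-hull span ratio,
   density and circularity, plus area and boundary-walk perimeter.

Statistics mirror the study design: Shapiro–Wilk-gated one-way ANOVA or
Kruskal–Wallis with Dunn's post hoc z-tests of every time point against the
0 s baseline (Bonferroni-adjusted, `*`/`**`/`***` at 0.05/0.01/0.001), and
one-sample t or Wilcoxon signed-rank tests of per-cell morphometric changes
against zero.

## Worked example

```r
library(photofade)

presets <- default_presets()
presets$a488
#> <fluorophore_preset 'a488'> k_fast=0.005846 k_slow=0 f_fast=0.698
#>   bg_residual=0.350 endpoint=900 s

acq <- acquisition_settings()             # 512 x 512, 8-bit camera model
scene <- make_microglia_scene(3, acq, seed = 9)
series <- generate_time_series(scene, presets$a488, acq, seed = 12)
loss_curve(series)[, c("t_s", "mean_intensity", "loss_pct")]
#>   t_s mean_intensity  loss_pct
#> 1   0       22.85075  0.000000
#> 2  30       21.17954  7.313593
#> 3  60       19.79253 13.383470
#> 4 120       17.63931 22.806429
#> 5 300       14.28478 37.486620
#> 6 600       12.79884 43.989437
#> 7 900       12.54501 45.100221
```

The loss column is the percentage of the initial whole-frame mean lost at
each cumulative illumination time: this single A488-calibrated series ends
at the 45% loss the preset was fitted to reproduce, and more than 10% is
already gone after 60 s. A full calibrated cohort run:

```r
cfg    <- calibrate_cohort(experiment_config())
report <- run_experiment(cfg)
summarize_run(report)$coverage     # mean |area change| per dye and time
report$pooled_change_pct           # pooled morphometric change per dye
#>      a488      a546
#> 13.745267  7.388209
```

The numbered scripts under `analysis/` run these stages with logging and
write tidy CSVs (`intensity_loss.csv`, `neuron_census.csv`,
`area_coverage.csv`, `fractal_changes.csv`, `statistics.csv`) under
`results/`.

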
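---
title: "Simulating photobleaching and its impact on morphometric readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating photobleaching and its impact on morphometric readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`photofade` asks a practical question: when an immunostained section sits
under the excitation beam while readouts are taken, how much of each
quantitative readout is already gone after 30, 60, 120, … 900 seconds of
cumulative illumination? The package answers it with a calibrated
simulation: synthetic fields of labelled cells are rendered through a
camera model under fluorophore-specific fading, and the same measurement
chain a microscopist would use — histogram means, nucleus counting,
background-cutoff segmentation, box-counting morphometry and the
accompanying statistical battery — is run on the fading frames.

## The generative model

### Bleaching kinetics

Fluorophore fading is modelled per pixel as a bi-exponential survival
fraction

$$d(t) = f_\text{fast}\, e^{-k_\text{fast} t} + (1 - f_\text{fast})\,
e^{-k_\text{slow} t},$$

the standard photophysics description of a mixed fluorophore population
(two rate constants in s⁻¹ and a mixing fraction; a mono-exponential dye
is the special case $f_\text{fast} \in \{0, 1\}$). The published decay
evidence for the two dyes is a descriptive second-degree polynomial on a
handful of time points, which has no generative interpretation; the
bi-exponential has enough freedom to pass through all printed points while
remaining monotone and positive. `fit_decay()` still reports the
descriptive quadratic and linear fits, as pure summaries of a loss curve.

### What a pixel sees

The expected pixel value at illumination time $t$ is

$$E[I(x,t)] = B + \big(D + S(x)\big)\, d(t),$$

with three components:

* $B$ — **non-bleaching background** (`background_level`, default 8
  intensity units): mounting-medium autofluorescence and camera offset.
  This is what remains of the frame mean when everything has bleached.
* $D$ — **diffuse bleachable staining**: spatially uniform non-specific /
  neuropil labelling. Real widefield immunofluorescence frames are
  dominated by this component; without it, a frame holding 2–5 microglia
  (a few percent of the pixels) could not lose 45–65% of its whole-frame
  mean, as the printed loss schedules require, unless cell amplitudes far
  exceeded the 8-bit range. $D$ is set per scene so that the bleachable
  share of the initial frame mean equals `signal_share` = 0.65.
* $S(x)$ — the per-pixel cell amplitude map of the scene.

The share 0.65 (equivalently a non-bleaching residual of 0.35) is pinned
by a plateau argument: the less photostable dye bleaches to invisibility
while its whole-frame loss plateaus at 65%, so 35% of the initial mean
never fades. The same mount and camera serve both arms, so the value is
shared; `calibrate_fluorophore()` can also fit it freely when its bounds
are left open, and the parameter-recovery tests exercise that path.

Noise follows the standard camera model: Poisson shot noise at
`photon_scale` = 4 photons per intensity unit, Gaussian read noise with SD
1.5 units, then rounding and clipping to 8 bits. Illumination is spatially
uniform (no flat-field information is available to emulate), and no
optical PSF is modelled.

### Scenes

Neuronal fields hold 12 non-overlapping neurons: an elliptical soma
(semi-major axis 9–14 px at the ~0.7 µm/px scale of the simulated 512×512
fields) containing a concentric flat nucleus of half the minor semi-axis.
Microglial fields hold 2–5 cells fully in frame: a soma disk (radius
4.5–6.5 px) with 3–6 primary processes growing as branched random trees
(segment length 7–14 px, branching probability 0.35 per segment, four
generations, widths tapering 3 px → 1 px).

Two intensity features matter for everything downstream:

* **Chord-profile rendering.** Somata and processes are solid bodies seen
  in projection, so their 2-D brightness falls from the structure axis to
  the silhouette edge as $\sqrt{1 - q^2}$. Every structure therefore owns
  a population of dim edge pixels, and raising a segmentation cutoff
  erodes structures gradually from their edges and tips — the mechanism
  that makes area coverage and single-cell area degrade smoothly rather
  than subtree-at-a-time. Nuclei are rendered flat: nuclear NeuN labelling
  is dense and, in practice, often saturating.
* **Bright/dim brightness mixtures.** Nucleus amplitude (neurons) and soma
  amplitude (microglia) are each drawn from a two-component lognormal
  mixture: a well-stained bright subset with fixed parameters (median 140
  and 150 intensity units, sdlog 0.25 and 0.30) and a weakly stained
  subpopulation whose weight, median and spread are the calibrated knobs.
  A single lognormal cannot reproduce the printed loss trajectories: the
  census curve is steep early and almost flat late, and the coverage
  targets require most mask pixels to hug the cutoff while a minority of
  cells stays bright enough to survive 300 s and to be profiled at the
  endpoint of detection. All amplitudes are capped at 230 units — staining
  saturation within the 8-bit budget.

## Calibration

`calibrate_cohort()` works in two stages so the intensity targets stay
independent of scene morphology.

**Stage 1 — kinetics.** Each preset's $(k_\text{fast}, k_\text{slow},
f_\text{fast})$ is least-squares fitted (multistart L-BFGS-B) to that
dye's printed whole-frame loss schedule: {30 s: 7, 60 s: 12, 120 s: 24,
900 s: 45}% for the A488-Plus-like dye and {30 s: 9, 60 s: 15, 120 s: 30,
900 s: 65}% for the A546-like dye. The 60/120/900 s values follow the
printed statements (both dyes lose more than 10% by 60 s, the loss doubles
by 120 s, final losses 45%/65%); the 30 s entries interpolate half of the
60 s value, since only significance, not magnitude, is reported there. A
warning is raised when the fit residual exceeds 2 percentage points RMS.

**Stage 2 — scene heterogeneity.** The weak-subpopulation knobs are fitted
by a coarse-to-fine grid search against the printed census targets
({60 s: 10, 900 s: 22}% for A488-like; {60 s: 10, 120 s: 20}% for
A546-like) and coverage targets ({60 s: 55, 300 s: 90}% for both). The
objective is evaluated by analytic predictors of the full measurement
chain rather than repeated simulation:

* the census predictor evaluates the capped mixture CDF at the exact
  detectability cutoff implied by the decay, the diffuse budget and the
  background statistics;
* the coverage predictor tabulates each reference cell's expected in-mask
  pixel count on a log-brightness grid — pixel inclusion probabilities use
  the exact Poisson ⊗ Gaussian tail near the cutoff, where the Gaussian
  approximation is visibly biased by shot-noise skew — and combines cells
  over fixed field compositions (common random numbers), so the objective
  is smooth and the brightness distribution is integrated analytically
  instead of sampled by a handful of scenes.

Both sides of the calibration see the same background estimator (histogram
mode with parabolic sub-bin refinement, plus 1.4826·MAD): an integer-bin
mode would quantise every derived cutoff to whole intensity units and make
per-field thresholds jitter by ±0.5 units. Grid refinement is clamped to
the original bounds, with a 0.3 floor on the weak-subpopulation sdlog —
unconstrained fits collapse to point masses that match the targets in
expectation but make per-seed census curves fragile, since every weak
nucleus then crosses the cutoff at once. The dim-weight scan runs upward
from 0.45 and stops at the first weight that fits within tolerance, which
keeps the largest feasible share of brightly stained (profile-quality)
cells. Fits are reported in `config$calibration`; a warning is raised when
a target is missed by more than `calib_tolerance` (default 5 percentage
points).

## Measurement chain

* **Intensity**: `mean_intensity()` is the plain mean over all pixels (no
  masking — deliberately including background, as the histogram-tool
  readout does); `loss_curve()` normalises to the 0 s frame.
* **Census**: `nucleus_detectable()` is a threshold proxy for the by-eye
  call — the nucleus mean must reach $\mu_b + 3\sigma_b$ of the *initial*
  frame's background and at least half its pixels must individually do so
  (`c = 3` is the conventional detection limit; `f_min = 0.5` lets partial
  fading defeat detection; both are knobs). Cells undetectable at 0 s are
  excluded from the denominator.
* **Coverage**: one cutoff $\mu_b + 3\sigma_b$ from the initial frame,
  applied unchanged to every later frame (`segment()` is a pure pixel-wise
  comparison; the `k = 3` multiplier is a knob because the original
  automated macro's constant is unpublished). The change versus baseline
  is reported as a magnitude, with the signed value retained in the CSV:
  under noise the curve need not be strictly monotone.
* **Morphometry**: profile extraction emulates the semi-manual single-cell
  segmentation. Each frame is thresholded against its *own* background
  statistics with multiplier `k_profile = 2` — an operator binarising a
  faded image adapts to its current contrast, and ~2 SD above background
  is the practical limit of visual separation — then `extract_profile()`
  restricts the mask to the cell's dilated truth support, applies a 3×3
  morphological closing and keeps the largest 8-connected component (the
  deterministic stand-in for manual continuity correction; reproducibility
  requires removing the human step). A cell qualifies for paired analysis
  when its profile holds at least `min_area = 400` px at both time points
  — roughly a soma (~95 px) plus half a typical branch tree, i.e. "visible
  soma and branch structure" — and the `n_select = 2` cells with the
  largest endpoint profiles per field are kept, mirroring the two profiles
  per image of the study design. Under the calibrated heterogeneity this
  yields fewer than the nominal 30 pairs per dye (typically 10–30), and
  the reported `n` follows the cohort, not the design.

### Box counting and hull descriptors

Box sizes form a geometric series from 2 px to 25% of the larger
bounding-box side (8 sizes where the profile permits) over `G = 4`
diagonal grid origins. The dimension is the OLS slope of $\ln N$ against
$\ln(1/\varepsilon)$ using, at each size, the *minimum* count over grid
origins — the most efficient cover. Both the 25% cap and the min-cover
aggregation exist for the same reason: partial boxes at the bounding-box
edge inflate counts at coarse scales and bias the slope (a filled square
fits at ~1.87 under a 45% cap with per-grid averaging, but at 1.98 under
this estimator; a straight line gives 0.99 and an order-8 Sierpiński
triangle 1.60 against the self-similarity value 1.585). Per-grid averaging
remains available as `fractal_dimension(cover = "mean")`. Lacunarity is
the mean over sizes and grids of $(\sigma/\mu)^2$ of the box masses over
occupied boxes, so an exactly tiled filled square scores 0.

Hull descriptors treat pixels as unit squares (the hull of all pixel
corners): span ratio is the longest hull axis (max Feret diameter) over
the smallest hull width (min Feret) — the "diagonal over short side"
convention, under which a 60×10 rectangle scores $\sqrt{60^2+10^2}/10 =
6.08$ and a disk 1.0; density is foreground count over hull area;
circularity is $4\pi\,\text{hull area}/\text{hull perimeter}^2$. The
profile perimeter is the outer-boundary walk length (Moore tracing, steps
of 1 and $\sqrt 2$), which differs systematically from pixel-edge
counting; a single-pixel profile falls back to its unit-square perimeter
of 4. Collinear profiles get a 1 px width floor in the span ratio.

### Statistics

`normality_gate()` routes to one-way ANOVA or Kruskal–Wallis (mid-ranks,
tie-corrected) by Shapiro–Wilk on every group at α = 0.05; zero-variance
groups force the nonparametric branch with a warning. Dunn's post hoc
z-tests compare each time point against the 0 s baseline only — matching
the figures, which star time points against baseline — with Bonferroni
adjustment over those comparisons (the adjustment method is a knob and is
recorded in the output). Paired morphometric changes are tested against
zero location by a one-sample t test when the changes pass the gate, else
the Wilcoxon signed-rank test; an all-zero change vector is reported
degenerate with p = 1. Stars follow the published thresholds (0.05, 0.01,
0.001).

## Determinism and degenerate inputs

Every stochastic step derives an integer seed from the master seed
(`experiment_config(master_seed = …)`), so a full run is bit-reproducible;
frames within a series are independent draws from per-frame derived seeds.
Degenerate inputs are contracts, not surprises: a zero-cell neuron scene
needs an explicit `allow_empty`; microglial fields must hold 2–5 cells;
placement failure after bounded rejection sampling names the density
limit; a constant frame yields σ_b = 0 with a warning and the cutoff falls
back to the background mean; an all-tied omnibus reports "ns"; a profile
smaller than the smallest box size is an error while a fully faded cell is
a distinct non-error signal (`is_faded()`).

## What the simulation does and does not establish

The generator reproduces the *calibration targets* by construction —
whole-frame losses, early census and coverage losses — so agreement there
validates the implementation of the measurement chain, not the biology.
The informative outputs are the quantities *not* calibrated: the full loss
trajectories between target times, the endpoint-of-detection morphometry,
and the relative ordering of readout robustness (intensity and coverage
degrade within a minute; nucleus counting with a photostable dye survives
with ~20–25% loss; per-cell shape parameters of still-binarisable cells
lose on the order of 10–20%).

Known limitations:

* The endpoint-of-detection morphometry is the least-constrained output,
  and the published endpoints were chosen at equal visual quality ("where
  binarisation still could be done") — implying both dyes' profiled cells
  were comparably degraded. Under the published intensity kinetics the
  two endpoints are *not* equivalent: the A546-like arm retains
  d(120) ≈ 0.55 of its signal while the A488-like arm retains
  d(900) ≈ 0.31. Simulated A546 profiles are therefore less degraded at
  their endpoint (pooled shape change below the published 12%), while
  borderline-brightness A488 cells are more degraded (per-cell area
  change above the published 18% whenever the cohort's field composition
  forces mid-brightness cells into the selection). Synthetic cells are
  also cleaner than tissue — no staining granularity, no overlapping
  out-of-frame processes, no focus drift — which damps the shape-metric
  changes at the shallow endpoint further.
* Nucleus counting and single-cell segmentation are by-eye judgements at
  the microscope; the 3σ detectability proxy and the 2σ profile
  binarisation are declared conventions, not inferences, and are exposed
  as knobs (`c`, `f_min`, `k`, `k_profile`).
* Whole-frame loss curves are insensitive to cell morphology by design
  (the diffuse component dominates), so they validate kinetics only.
* The box-counting conventions (size range, grid count, hull-based density
  and circularity) are fixed for determinism; the original plugin's
  version-dependent defaults are unknown.

## Problem sizes

The default study runs 15 fields per staining per dye at 512×512 px with
the 7-point schedule — the full design — in roughly half a minute of
measurement plus a few minutes of calibration on one CPU. The test suite
exercises the full calibrated cohort once in its acceptance file and uses
quarter-size fields (256×256, 3 replicates, shortened schedules, smaller
microglia) for pipeline-level properties such as byte-stability, where the
property being checked does not depend on the field scale; analytic-shape
checks (Sierpiński order 8, 256 px squares and lines, rectangles and
disks) use the sizes at which their reference values are sharp.
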
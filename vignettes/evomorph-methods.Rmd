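---
title: "Models and methods behind evomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

When *Escherichia coli* is evolved by daily serial transfer on oleic-acid
vesicles (OAVs) as the sole carbon source — a regime mimicking a primordial,
fatty-acid-rich environment — its shape drifts from the canonical rod toward
a sphere while its growth rate rises. The quantitative backbone of that
claim is a single-cell analysis chain: imaging flow cytometry produces tens
of thousands of event images per population; events are gated for quality;
morphometric features are extracted; per-transfer population summaries are
assembled into lineage trajectories; and trend, fold-change, correlation and
group-comparison statistics turn those trajectories into the headline
results. evomorph implements that chain end to end, together with a
synthetic-data generator that emulates both the evolution experiment and the
instrument, so every stage can be validated against known ground truth.
Nothing in the analysis code reads the generator's truth labels; they exist
only so tests can score recovery.

# The morphometric model

A bacterial cell image is modelled as the 2D projection of a spherocylinder
of length $L$ and width $W$: a capsule, i.e. a $(L-W) \times W$ rectangle
with two half-disc caps of diameter $W$. The features per event are

* $L$, $W$: major and minor axis lengths (µm) — the longest and narrowest
  dimensions of the cell image;
* $A$: projected area, the segmentation-mask pixel count times the pixel
  area (0.09 µm² at the instrument's 60× magnification);
* aspect ratio $AR = W/L \in (0, 1]$ — 1 is a sphere, values far below 1 a
  rod;
* volume $V = \frac{\pi}{6} L W^2$ (µm³), exactly the sphere volume when
  $L = W$;
* $A/V$ (µm⁻¹): the surface-availability proxy. Note that $A$ is a
  *projected 2D area*, not a 3D surface area, so $A/V$ deliberately mixes a
  2D and a 3D quantity; it is implemented exactly as defined because that is
  the statistic the downstream comparisons use. For fixed $W$, $A/V$
  increases with $L$, so the rod-to-sphere transition lowers $A/V$;
* GFP$_{\text{total}}$ and GFP$/V$: integrated fluorescence over the
  (slightly dilated) mask and its ratio to $V$, the protein-abundance proxy.

## Axis extraction

The axis estimator matters more than it looks: population means are taken
over ~10,000 events, so their standard errors are of order 0.5%, and any
estimator bias at the instrument's 0.3 µm pixel (a cell is only 3–10 pixels
wide) dominates the error budget. Three estimators are provided
(`extractAxes()`):

* **`capsule` (default)** — a least-squares fit of a capsule edge-profile
  model to the intensity image, by Levenberg–Marquardt with an analytic
  Jacobian. The model is the signed distance $d$ to a capsule boundary
  passed through a Gaussian edge profile $\Phi(-d/\sigma)$, with centre,
  orientation, half-length $a \ge 0$, radius $r$, edge width, amplitude and
  background as free parameters ($L = 2a + 2r \ge W = 2r$ by construction,
  so the ordering constraint is built in rather than enforced by a penalty
  wall). This is the approach rod-shaped-bacteria morphometry tools take
  (model fitting for subpixel accuracy). It is exact on noiseless rendered
  capsules and biased well below 0.5% at 5% intensity noise.
* **`contour`** — model-free: the half-maximum contour of the
  spline-upsampled image, with $L$ the angle-refined rotating-caliper
  maximum extent and $W$ twice the largest-inscribed-disc radius. Accurate
  to ~1–3%; used as a cross-check and for non-capsule shapes.
* **`moment`** — the intensity-weighted second-moment-equivalent ellipse
  axes. This classical definition overestimates both axes of an elongated
  capsule by 8–16% at 0.3 µm pixels (the capsule's mass distribution is not
  an ellipse's), which is why it is not the default; it is retained for
  sensitivity analysis and as the initializer of the model fit.

## Segmentation

Events are segmented by a half-maximum rule: an Otsu split separates
foreground from background, and the final threshold is placed halfway
between the background level and the foreground plateau (90th percentile of
foreground pixels). A raw Otsu threshold lands well below the half maximum
on small cells, whose images are mostly edge pixels, and inflates the
projected area by up to ~25%; referencing the plateau keeps the pixel-count
area faithful. The largest connected component is kept, holes are filled,
and events are flagged empty (and excluded) when the foreground is tiny
(< 5 px), low-contrast, fragmented (largest component under half the
foreground), or non-compact — the signatures of a pure-noise image.

Pixel-count areas at a 0.3 µm pixel necessarily carry quantization jitter of
a few pixels per event (a few percent for a 3 × 1 µm cell, more for a 1 µm
sphere); the jitter averages out in population summaries and shrinks
linearly with pixel size, which the tests verify at two resolutions.

# Event gating

Three gates reproduce the instrument-software workflow, in order:

1. **fluorescence intensity** ≥ `fluorescenceMin` — removes calibration
   beads (bright in other channels but dim in the GFP channel) and dim
   culture debris;
2. **aspect-ratio intensity** within bounds — the aspect ratio of the
   intensity-weighted second-moment ellipse of the fluorescence image; the
   instrument names this feature without publishing a definition, so the
   second-moment ellipse, the standard moment-based shape score, is used;
3. **gradient RMS** ≥ `gradientRmsMin` — image sharpness: the RMS of the
   finite-difference gradient magnitude (central differences inside,
   one-sided at borders) over the event bounding box, after normalizing the
   image by its maximum so the score is gain-invariant. Out-of-focus events
   score roughly threefold lower than in-focus ones.

The instrument's numeric thresholds are not published. The defaults in
`GateConfig()` were calibrated once against the simulator's labelled default
output (in-focus cells' gradient RMS never fell below 0.186 while
out-of-focus events never exceeded 0.128, hence 0.155; analogous margins for
the intensity gate) and are expected to be overridden per dataset. On
labelled synthetic populations the defaults remove > 99% of
beads/debris/out-of-focus events while losing < 1% of in-focus cells;
populations whose GFP concentration drifts very low can lose a few percent
of their dimmest cells, which is the realistic cost of an intensity gate.

# The synthetic experiment

The generator plays the serial-transfer protocol forward explicitly rather
than drawing summary numbers:

* **Parameter trajectories.** True mean length/width, growth rate and GFP
  concentration relax exponentially from ancestral values toward evolved
  targets with a configurable half-life. The experiment's published
  trajectories are saturating but come with no generative model; exponential
  relaxation is the simplest two-parameter monotone law with that shape.
* **Daily transfers.** Each day three candidate dilutions are grown 24 h
  (logistic toward the stationary density, default 10⁸ cells/mL) and the
  culture still in exponential phase (≤ half the stationary density) whose
  density is closest to the 10⁷ cells/mL exponential target is selected.
  Post-dilution densities below the 10⁴ cells/mL drift floor are
  inadmissible. By default the three factors bracket the regrowth predicted
  from the previous day's growth rate, as in a protocol whose dilution rates
  are estimated daily; a fixed-factor mode exists. Cumulative generations
  are $\sum \log_2(\text{daily regrowth fold})$, exactly.
* **Protocol arithmetic constrains the rates.** Keeping a 24 h cycle between
  a 10⁴ cells/mL floor and a ~10⁷ cells/mL target caps the growth rate at
  $\ln(1000)/24 \approx 0.29\,h^{-1}$. Defaults were chosen inside that
  envelope: OAV arm 0.10 → 0.16 h⁻¹ and glucose arm 0.18 → 0.28 h⁻¹ (both
  ~1.6-fold, matching the observation that fitness gains were equivalent
  across carbon sources), morphology 3.0 × 1.0 µm → 1.5 × 1.0 µm in OAVs
  (length shrinks, width constant) and unchanged in glucose, GFP
  concentration 100 → 60 a.u./µm³ in OAVs and 100 → 130 in glucose. Over the
  default 100 transfers this accumulates ≈ 450–500 generations.
* **Lineage variability.** Independent lineages scale their programmed
  effects (target − start) and half-life by a lognormal factor (8% CV). The
  jitter multiplies the *effect*, not the target, so an arm with no
  programmed shape change stays trend-free — important, because the glucose
  arm is the negative control for the correlation analysis.
* **Populations.** Cell lengths/widths are lognormal about the true means
  (15% CV, $W \le L$ enforced by resampling), orientations uniform, GFP
  lognormal (20% CV). Contaminants are interleaved at the declared
  fractions: calibration beads (1 µm sharp discs, dim in the GFP channel),
  culture debris (irregular dim multi-lobe blobs), and out-of-focus cells
  (2 px defocus). Defaults: 5% / 5% / 10%.
* **Rendering.** Capsules are drawn with anti-aliased Gaussian edges
  (σ = 0.5 px); total fluorescence integrates to
  $\text{GFP} \times V \times \text{gain}$ before 5% multiplicative noise
  plus a small additive background. Defocus widens the edge-spread profile
  rather than convolving the image — for a convex capsule the two are
  nearly identical and the former is much cheaper ("effective edge-spread
  model").

What the generator does *not* emulate: optics-accurate point-spread
functions, camera-specific noise statistics, cell-cycle-linked size/GFP
correlations, pixel saturation, doublets and clumps, or any genetics.
Passing tests therefore demonstrate that the pipeline's estimators and
statistics are correct and well-calibrated on data with known truth — not
that they are robust to every artefact of real instrument data.

# Growth and capacity analysis

* **Growth rate** (`fitGrowthRate`): the slope of ln(density) vs time over
  the sliding window (default 5 points) that maximizes the slope subject to
  $R^2 \ge 0.99$; if no window passes, the best-$R^2$ window is returned
  with a low-confidence flag. The originating study cites an external
  procedure without reproducing it, so this algorithm is fixed and
  documented here; it is exact on exponential data and within 2% on
  logistic curves sampled every 0.5 h.
* **Carrying capacity** (`carryingCapacity`): maximum of the 3-point
  median-smoothed density series divided by the carbon concentration (mM).
  The smoothing guards single-point spikes; whether the original analysis
  smoothed is unstated, so the smoothed maximum is this package's
  documented choice. A maximum falling on the final point is flagged as "no
  plateau". OD-mode curves yield only relative capacities and are flagged.
* **Carbon normalization** (`normalizeCarbon`): glucose C₆H₁₂O₆ → 6
  carbon-mM per mM, oleate C₁₈H₃₄O₂ → 18, making the assay's two
  concentration ladders (0.035–3.5 mM OAV, 0.105–10.5 mM glucose)
  element-wise equal in carbon equivalents.
* **Capacity trend** (`fitCapacityTrend`): least-squares cubic in
  log₁₀(concentration), the "theoretical analysis" used to summarize the
  capacity trade-off across the ladder.

# Trajectory statistics

* **Logarithmic trends** (`fitLogTrend`): $y = a\ln x + b$ with the
  abscissa shifted to start at 1 (the published plots do not state the
  regressor offset; starting the index at 1 is the convention here).
  `extrapolateTrend` evaluates the fit at future indices — increasing
  whenever $a > 0$, the basis of the "extended evolution would continue the
  trend" prediction.
* **Fold changes** (`foldChanges`): endpoint population mean over the
  common-ancestor mean, one ratio per lineage, grouped by arm.
* **Group comparison** (`permutationTest`, `compareFoldChangeGroups`,
  `compareGroups`): the study reports p-values without naming a test. With
  six lineages per arm, complete enumeration of all $\binom{12}{6} = 924$
  relabellings is feasible, so a two-sided exact permutation test on the
  difference of group means is the default — assumption-free and exactly
  calibrated (the null rejection rate at $\alpha = 0.05$ is 46/924 ≈ 0.0498
  by construction, which the calibration tests confirm empirically). A
  Welch t-test is reported alongside as a parametric cross-check; neither
  is claimed to reproduce the published p-values numerically. Larger groups
  fall back to Monte Carlo with the add-one estimator. Paired comparisons
  use exact sign-flip enumeration up to n = 14.
* **Correlations** (`featureCorrelations`): Pearson over the measured
  transfers of one lineage for the six features (growth rate, aspect ratio,
  length, width, log area, log volume); Spearman available. The published
  heatmap does not state whether transfers were pooled within or across
  lineages; the per-lineage convention is implemented, and pooled records
  can be passed directly. No multiple-testing correction is applied by
  default, matching per-pair reporting; `p.adjust` can be applied to the
  p-matrix. Pairs with a constant feature are undefined: r = NA, p = 1.
* **Quartiles** (`summarizeBoxes`): linear-interpolation (type 7)
  quantiles, stated explicitly for cross-language parity.

# Numerical choices and degenerate inputs

* Volume and aspect ratio reject non-positive dimensions and violations of
  $W \le L$; a single-pixel mask returns $L = W =$ one pixel side.
* The capsule fit falls back to moment axes if the optimizer fails
  (virtually never on gated events).
* The permutation p-value counts the observed labelling among the splits,
  so $p \ge 1/n_{\text{splits}}$ and identical constant groups give exactly
  $p = 1$; ties in the statistic are counted with a relative tolerance of
  $10^{-12}$.
* `gradientRMS` of a constant or single-pixel image is 0 by convention.
* Logistic growth curves with empty time grids, inoculum ≥ capacity, or
  non-positive rates are rejected at construction.

# Problem sizes used in validation

The test-suite's end-to-end run uses 6 + 6 lineages, 60 transfers measured
every 6th at 80 events per measurement; the acceptance script runs the full
study design (100 transfers measured every 5th, 100 events per measurement,
~10,000-event populations for the recovery and gating checks; 2000–2000×15
replicates for the permutation and correlation calibrations). These sizes
were chosen so each stage's statistical claims are testable with comfortable
margins while a complete validation run stays in the minutes range on a
single CPU; the scientific conditions (six lineages per arm, ~500
generations, ~10⁴-event populations, contaminant mix) follow the study
design the simulator emulates.

# Known limitations

* The area feature is a raw pixel count at a coarse pixel; per-event areas
  jitter by a few percent and single-event $A/V$ values inherit that
  jitter. All published-style conclusions use population means, where the
  jitter is negligible.
* The capsule model fit assumes a convex spherocylinder; bent or dividing
  cells are measured as their best-fitting capsule. The `contour` estimator
  is the model-free alternative.
* The moment-ellipse axis definition is retained for comparability but is
  known-biased at this pixel scale; do not mix estimators within one
  analysis.
* Gating with an intensity floor removes the dimmest cells of very
  low-expression populations (a few percent), slightly truncating the
  GFP/V distribution — as any real intensity gate does.
* The exact permutation test's p-values are discrete (multiples of 2/924
  for 6 vs 6); "p < 0.05" effectively means p ≤ 0.0498.
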
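---
title: "Quantifying tissue homogeneity in confocal laser endomicroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue homogeneity in confocal laser endomicroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

Probe-based CLE produces gray-scale fluorescence frames of the superficial
mucosa at a fixed focal depth (here 55–65 µm, 240 µm field of view, 1 µm
resolution, Cellvizio-style hardware). After intravenous fluorescein, the
dye outlines intercellular spaces: healthy squamous epithelium appears as a
honeycomb of bright borders around dark cells, while squamous cell
carcinoma (SCC) shows smudged borders, leakage and — the property exploited
here — strong *regional* intensity variation across even a 240 µm field.

The analysis reduces each sequence to one number. Four square ROIs of
45 µm × 45 µm are placed flush in the frame corners (the most mutually
distant placement, so regional variation is sampled maximally). For frame
$f$ with ROI means $\mu_1(f),\dots,\mu_4(f)$:

$$ s(f) = \sqrt{\tfrac{1}{3}\sum_{r=1}^4 (\mu_r(f) - \bar\mu(f))^2 },
   \qquad S = \tfrac{1}{60}\sum_{f=1}^{60} s(f). $$

$S$ (the *mean spread*) is the per-sequence homogeneity statistic; the
pooled ROI mean $\tfrac{1}{4\cdot 60}\sum_{f,r}\mu_r(f)$ summarizes overall
signal. A sequence is called *inhomogeneous* iff $S$ strictly exceeds a
cutoff; a value exactly at the cutoff is homogeneous (a deliberate, exact
tie-break).

Assumptions worth stating: the ROI mean is the plain arithmetic mean of
pixel gray values (viewer software sometimes reports histogram-binned
estimates; at 2025 pixels per ROI the difference is negligible); the SD
uses the sample convention ($n-1$, here $n=4$) — the alternative $n$
denominator rescales every spread by the same $\sqrt{3/4}$ and cancels in
all between-class comparisons, but the convention matters when comparing
numbers across software; and intensities live on the 16-bit Cellvizio
scale (class means near 232 and 467 exceed 8-bit range).

## Tunable parameters

* `roi_side_um = 45` (µm): ROI side; pixels per side is the nearest integer
  of `roi_side_um / pixel_size_um` (half away from zero, minimum 1).
* `inset_um = 0`: ROIs sit flush at the corners. A nonzero inset supports
  circularly masked exports, at the cost of sampling less mutually distant
  regions.
* `threshold = 70.3` (gray value): midpoint of the two class presets
  (39.1, 101.5). The study that motivates the package defines no automatic
  cutoff; the midpoint is reproducible and assumption-light.
  `fit_threshold()` offers a Youden-optimal alternative on labeled data
  (ties broken toward the smaller cutoff).
* Flooding detection (`detect_flooding`): baseline window 30 s, onset
  threshold `k_sigma = 3` baseline SDs sustained for 5 frames, adequate
  quality at `plateau_frac = 0.9` of the baseline-to-plateau rise, plateau
  estimated from the final decile of the trace. The onset rule is a
  conventional change-point heuristic; the sustain requirement suppresses
  single-frame noise, and the plateau's final-decile estimate biases the
  adequate time slightly early (about one ramp time-constant percent),
  which is why recovery is quoted to ±2–3 s.
* QC flags (`sequence_stats`): frame $f$ is flagged when the across-ROI
  average jumps by more than 5 robust SDs (1.4826 × MAD of all
  frame-to-frame changes in the sequence). Purely advisory — frames are
  never dropped automatically, mirroring how sequences were curated by hand
  in the emulated study.

## What the synthetic generator emulates

No CLE videos of this kind are publicly deposited, so the package ships a
generator whose output has the *statistical* structure the analysis
assumes; texture realism is explicitly not a goal.

* **Benign frames**: a jittered hexagonal Voronoi tessellation (cells
  20 µm, border bands 3 µm) with log-normal per-cell brightness, dark
  interiors at 12% of border brightness, and no deliberate regional field.
  Corner-ROI dispersion arises from sampling ~6 cells per ROI.
* **SCC frames**: the same machinery disorganized — jitter comparable to
  the cell spacing, wider borders, brighter interiors ("smudged"), Poisson
  fluorescein-leakage blobs, and a random low-frequency intensity plane
  that drives corner-to-corner divergence.
* **Calibration**: frames are synthesized on a normalized texture scale and
  mapped to gray values affinely, `gain * texture + offset`. The two
  constants per class are solved so the *expected* pooled ROI mean and
  *expected* mean spread equal the presets (232.1/39.1 benign,
  467.3/101.5 SCC), using the normalized texture's corner-ROI moments
  estimated from 1500 dedicated calibration frames per class
  (`calibration_frames`; at that size the calibration SE is ~0.5% on the
  mean and ~1.3% on the spread, and `frame_calibration()` reports both so
  recovery checks can fold them into their tolerances). Because the
  mapping is affine and estimated from a separate substream, recovery of
  the presets through the ROI pipeline is a genuine check, not a fit to
  the test.
* **Kinetics**: the wash-in ramp is $r(t) = 1 - e^{-((t-t_0)/\tau)^q}$
  with $r = 0.9$ at the adequate time by construction (defaults: onset
  208 s, adequate 224 s, exponent $q = 1$). Rendered frames are
  `baseline + noise + r(t) * template`.
* **Artifacts**: blood/dirt (dark blotches), saliva (low-contrast veil),
  air bubble (dark disc, bright rim), contact loss (collapse to baseline
  noise), tangent probe position (linear intensity ramp with closed-form
  corner response), and motion. Motion is modeled as *whole-frame*
  slippage — a directional running-average smear plus a brightness gain —
  because a band covering only part of the frame can brighten exactly the
  dimmer corners and reduce the spread; whole-frame slippage inflates the
  spread in ≥ 99% of trials, matching the qualitative claim that motion
  artifacts masquerade as inhomogeneity.
* **Raters**: independent Bernoulli calls at per-rater operating points
  taken from the printed observer counts.
* **Study design**: 27 benign + 33 SCC sequences × 60 frames at 12 Hz
  (60 frames over 5 s). Whole-recording frame counts in the emulated
  study's case table imply ~8 Hz for the *full* recordings; the 12 Hz
  sequence-level rate is used because the unit of analysis is the selected
  5-s sequence.
* **Defaults deliberately off**: `artifact_probs` are all zero because the
  emulated sequences were manually selected artifact-free representative
  material, and the intensity presets describe those selected sequences.

What the generator does **not** model: temporal correlation within a
sequence (frames are i.i.d. draws, so per-sequence variances are somewhat
larger than in real video where the same tissue persists across frames);
vessels and capillary loops; dysplasia or carcinoma in situ; probe optics
(vignetting, circular field mask); and any texture property beyond the
first- and second-order corner-ROI statistics. Consequently, passing
recovery tests shows the *pipeline* is correct and well-calibrated — it
does not show that real patient material separates this cleanly. On the
synthetic study the default cutoff classifies perfectly, whereas human
raters on real video reach 81.8%/86.2%; the gap is a property of the
synthetic material's cleanliness, not evidence about the method.

## Numerical and statistical choices

* **Welch t-test** for the class comparisons (the printed class SDs differ
  ~3-fold; the conclusion is insensitive to the choice). Degenerate case:
  two constant samples with equal means give $t = 0$, $p = 1$; with
  different means the statistic is undefined and an error is raised.
* **Pearson chi-square without continuity correction** on 2×2 tables
  (all observer-table cells are large); zero marginals are input errors.
* **Wilson score intervals** for sensitivity/specificity. The choice is
  forced by reverse-engineering: under the display convention below it
  reproduces the printed pooled bounds (76.3, 86.2, 80.6, 90.4) exactly.
  Boundary counts return exact 0/1 endpoints.
* **Display rounding**: percentages are *truncated* toward zero to one
  decimal (48.148 → 48.1, 78.78 → 78.7), the convention evident in the
  printed observer table. Raw proportions are always kept alongside.
* **Fleiss kappa** with the two-category formula; when every rating falls
  in one category the chance-agreement denominator vanishes and the
  documented convention returns κ = 1 (observed agreement is then
  necessarily 1). Landis–Koch bands use inclusive upper bounds
  (≤ 0.20 low, ≤ 0.40 fair, ≤ 0.60 moderate, ≤ 0.80 substantial,
  ≤ 1 almost perfect); negative κ maps to "low" with a warning.
* **Observer counts, not printed percentages**: a few published display
  values are internally inconsistent with their own counts (a sensitivity
  printed as 59.1% against 15/33 = 45.4%, one 90.0% against 30/33 = 90.9%,
  and a pooled 14.8% against 26/189 = 13.7%). All metrics here are
  recomputed from the counts; the count-derived values are the ones the
  other printed ranges corroborate.
* **Determinism**: every stochastic stage draws from a substream derived
  from the study seed by counter (sequences, calibration, rater
  simulation), so studies are bit-reproducible and adding sequences never
  perturbs earlier ones.
* **Problem sizes**: the shipped analyses use the full 3600-frame design,
  1500 calibration frames per class, 400 simulated rater panels for the
  kappa check, and a 260 s / 1 Hz rendering for flooding recovery — sizes
  at which every Monte-Carlo SE is a small fraction of its target and a
  full run stays in the low minutes on one core.

## Known limitations

* The exact published inter-rater κ = 0.53 cannot be reproduced: the
  item-level rating matrix was never released. The package instead checks
  that independent Bernoulli raters at the printed operating points yield
  a κ distribution whose central 95% interval covers 0.53 (it does, near
  its upper edge — real raters presumably share item-level difficulty,
  which pushes agreement above independence).
* Image-derived statistics of the real patient videos are unreproducible
  (no deposition); all image-level results here are synthetic by design.
* The homogeneity statistic is intentionally a single criterion. On real
  material it is vulnerable to exactly the artifacts the compositor
  models; the QC flags advise but do not adjudicate.
* Whether the published "±" values on the class statistics are SDs or SEMs
  (and over frames or sequences) is ambiguous in the source; the generator
  calibrates class *means* only and makes no claim about matching those
  dispersions.
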
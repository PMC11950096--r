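---
title: "Methods: quantifying HER2 dual-colour bright-field ISH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying HER2 dual-colour bright-field ISH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ishquant)
```

## The measurement problem

HER2 amplification testing by bright-field dual-colour ISH counts two
chromogenic probes per tumour nucleus: the *HER2* locus (silver chromogen,
discrete black dots) and the chromosome-17 centromere CEP17 (red
chromogen), over a hematoxylin counterstain. A case is summarised by the
mean HER2 and CEP17 copies per cell and by the HER2/CEP17 ratio, and the
2023 ASCO/CAP breast guideline maps the pair (ratio, mean HER2) onto five
ISH groups. Visual scoring counts 20–60 cells; an image-analysis pipeline
can score thousands, shrinking the 95% margin of error of these estimates
(ME = 1.96·SD/√n) by an order of magnitude. This package implements the
full pipeline — stain separation, nuclear segmentation, signal counting,
scoring, classification — plus the agreement statistics used to validate
such a pipeline against visual reads, and a synthetic-slide generator
that provides exact ground truth for testing.

## Pipeline model and assumptions

`run_case()` composes the stages below. The pipeline is fully
deterministic: randomness exists only in the synthetic generator, under a
single recorded seed.

### Stain separation

Bright-field absorbance is modelled in optical density, OD =
log10(white/I), with the white point estimated robustly from the tile
(median luminance of near-white pixels; fixed fallback 240/255 with a
warning when less than 1% of the tile is near-white, as in a tile fully
covered by tissue).

* **Hematoxylin** is recovered by linear colour deconvolution against a
  configurable stain matrix. The default hematoxylin OD vector
  (0.650, 0.704, 0.286) is the standard published value; no vendor
  vectors exist for this assay, so the matrix is exposed in
  `ish_config()$stain`. The counterstain map is attenuated where a
  chromogen score dominates, reflecting physical occlusion of the
  counterstain by chromogenic deposits.
* **HER2 (silver)** is deliberately *not* deconvolved: the silver
  chromogen is achromatic, so it has no stable OD direction and is
  instead scored by a luminance–colourfulness rule: full score when
  relative luminance is below half of `dark_luminance_max` (default
  0.45) *and* chroma (max − min channel, relative to the white point) is
  below half of `dark_saturation_max` (default 0.25), falling linearly
  to zero at the thresholds. Chroma is used rather than HSV saturation
  because the HSV denominator (max channel) is tiny for dark pixels,
  which makes HSV saturation noise-dominated exactly where the silver
  signal lives. The score is monotone: darkening a pixel at fixed chroma
  never decreases it.
* **CEP17 (red)** is scored by hue proximity to red (within
  `red_hue_halfwidth_deg`, default 40°) gated by HSV saturation
  (`red_saturation_min`, default 0.30) away from the background.

All soft scores are ramps, not hard thresholds, so downstream blob
thresholds remain meaningful on partially saturated pixels. Background
pixels are forced to zero on all maps.

### Nuclear segmentation and the size gate

The hematoxylin map is smoothed (Gaussian, `smooth_sigma_um` = 0.5 µm),
thresholded — by default against a Gaussian-weighted local mean
(`adaptive_window_um` = 12 µm, offset 0.05, with a global floor of 0.15
so empty background never triggers) — hole-filled (chromogenic dots punch
holes in the counterstain), opened, and split by a distance-transform
watershed (tolerance `watershed_tolerance_um` = 1 µm). Labels are dense
and ordered by centroid (y, x) so runs are comparable.

The nuclear size gate keeps the **closed interval [30, 150] µm²**:
areas strictly below 30 µm² are mostly stromal and inflammatory nuclei,
areas strictly above 150 µm² are mostly under-split nuclear clusters.
Keeping the endpoints follows from the rule being stated as rejection of
values *below* 30 and *above* 150. The gate runs after watershed
splitting (whether the original commercial tool gated before or after
splitting is not documented anywhere we know of; gating after splitting
is the choice here because the areas being gated are then the areas
actually quantified). Nuclei touching the tile border are excluded by
default (reason code `BORDER`) because their area is censored, which
would bias the gate; this is configurable. Nuclei whose centroid falls
outside the region of interest are flagged `OUTSIDE_ROI`.

The size gate is an intentionally crude cancer-cell classifier: on mixed
scenes its sensitivity/specificity against ground truth can be measured
with `inclusion_performance()` and converted to a positive predictive
value at any cancer cellularity with `diagnostic_metrics()`; the package
reproduces the *procedure*, not any cohort's particular values.

### Signal detection, doublets, clusters

Each channel map is thresholded (`blob_threshold` = 0.5) and connected
components become signal calls; components smaller than `min_speck_um2`
(0.1 µm²) are discarded as sub-resolution noise. Three rules then refine
counts:

* **Doublets.** A replicated locus appears as two adjacent dots that must
  be counted as one signal. Calls closer than `doublet_sep_um` merge;
  merging takes connected components of the close-pair graph, so the
  result is independent of input order. The default separation, 0.8 µm,
  is about one dot diameter (0.6 µm) plus margin; the counting rule is
  standard but no published distance exists, so the threshold is exposed
  in configuration.
* **Clusters.** In highly amplified cells HER2 signals fuse into blobs
  that cannot be enumerated. Any non-doublet call larger than
  `cluster_factor` (2.5) times the reference single-signal area gets
  `round(area / reference)` signals (minimum 2). The reference area is
  self-calibrating — the slide median of isolated single calls — with a
  configured fallback (0.28 µm², the area of a 0.6 µm dot) when fewer
  than 10 isolated calls exist. `round()` follows R's half-to-even rule;
  blob areas essentially never sit exactly on a half-integer multiple.
  No cap is applied to per-cell counts in massive clusters; counts are
  reported as estimates.
* **Assignment.** A call belongs to the nucleus whose mask contains its
  centroid ("signals within the nucleus"); centroid containment is cheap,
  deterministic, and unambiguous because nucleus masks are disjoint.
  Stray calls are dropped and counted.

### Scoring and classification

Only cells with ≥1 copy of HER2 *and* ≥1 copy of CEP17 are scored (zero
HER2 is checked first for the reason code). Case-level quantities over
the n scored cells:

* mean_her2 = Σh/n, mean_cep17 = Σc/n;
* **ratio = Σh / Σc**, the ratio of totals. This equals the ratio of the
  means and matches guideline arithmetic; the alternative (mean of
  per-cell ratios) is biased upward by low-CEP17 cells. The per-cell
  ratios h_i/c_i are still used for the spread of the ratio, because a
  margin of error for the ratio needs a per-cell dispersion; this choice
  is isolated in one function and documented here.
* margins of error ME = 1.96·SD/√n with the sample SD (n−1). The
  critical value is fixed at 1.96 (no t-correction at small n) — the
  stated formula of the procedure being reproduced. ME is undefined at
  n = 1 and reported missing; n < 20 raises a low-cell-count warning,
  20 being the minimum cells of a visual ISH read.

`classify_ish_group()` applies the five-group partition with boundaries
classifying upward (ratio exactly 2.0 and mean HER2 exactly 4.0/6.0 go to
the higher group) — the standard reading of the guideline's "≥"; no
published worked example sits exactly on a boundary, so this is a
documented convention rather than a testable fact. `her2_status()`
implements the IHC 2+ (equivocal) context only: groups 1 and 3 positive,
groups 2, 4, 5 negative.

## The synthetic-slide generator

`generate_case()` renders what the pipeline assumes: white background
(intensity 250), elliptical hematoxylin-stained nuclei (OD 0.45 with
±10% per-nucleus jitter through the published hematoxylin vector),
near-achromatic dark dots (RGB 40,40,40) and red dots (RGB 190,45,55) of
0.6 µm diameter placed inside nuclei, additive Gaussian noise (SD 2
grey levels), at 0.121 µm/px. Defaults model the study conditions the
pipeline targets:

* cancer nuclei lognormal with median 80 µm² (sdlog 0.3), non-cancer
  median 20 µm² — the two populations straddle the 30 µm² cutoff so the
  gate is genuinely exercised;
* copy numbers per cancer cell from a constant or truncated-Poisson law
  (minimum 1 by default; minimum 0 available to exercise the scoring
  exclusions); non-cancer cells are diploid;
* a doublet rate (default 0.1) rendering single signals as touching dot
  pairs, and a cluster rate rendering a cell's HER2 complement as one
  blob of k× the single-dot area — giving the cluster estimator an exact
  truth.

Ground truth records, per nucleus, the true copy numbers *and* the
rendered blob counts, so conservation can be checked at both levels.
Identical parameters and seed give bit-identical rasters and truth
tables; the logged `params.json` regenerates a fixture exactly (area
laws are parameterised by median rather than log-mean so the logged
parameters are exact decimal numbers).

What the generator does **not** emulate: tissue texture, out-of-focus
optics, stain bleed-through, overlapping nuclei in z, scanner
compression artefacts, and the full morphological diversity of tumour
nuclei. Tests passing on synthetic scenes therefore demonstrate the
correctness of the *algorithms and bookkeeping* (segmentation splitting,
gating, doublet/cluster rules, conservation, classification), not
clinical-grade performance on real slides, which requires tuning the
exposed configuration on real material.

## Numerical and design choices

* **Power-model fit in log-log space.** `fit_power_model()` least-squares
  log(ME) = log β0 + β1·log n, the classical curve-estimation procedure,
  with R² in log space (whether the reference procedure computed R² in
  raw or log space is unstated; log space is the choice here and makes
  the fit exactly linear). On exact power-law data the fit recovers
  (β0, β1) to 10⁻¹⁰ relative error, which the tests assert.
* **Minimum-cell solver.** `min_cells_for_me()` inverts the fitted curve
  in closed form, n = ⌈(t/β0)^{1/β1}⌉, then walks the integer boundary
  to guard floating-point rounding, guaranteeing ME(n) ≤ t < ME(n−1).
* **Margins of error over iid per-cell draws** scale as n^(−1/2); the
  fitted exponent on simulated per-cell counts is asserted to lie in
  [−0.6, −0.4]. Empirical ME curves from heterogeneous cases fit
  shallower or steeper exponents; the package treats the exponent as a
  fitted quantity, never a constant.
* **Bland-Altman sign convention**: differences are test minus reference
  (image analysis minus visual), so a pipeline reading lower than the
  visual count yields a negative mean difference.
* **Kappa**: standard two-rater 2×2 Cohen's kappa; the degenerate
  p_e = 1 case returns 1 for perfect agreement. No confidence interval
  is implemented.
* **Predictive values** use Bayes' rule at a *stated* prevalence rather
  than the study sample's, so a validation cohort enriched for positives
  can still report deployment-relevant PPV/NPV; a zero denominator
  yields NA, not 0.
* **Configuration** is a validated nested list (YAML or JSON on disk;
  YAML is the package's config format choice for comments and
  readability) with unknown keys rejected and precedence CLI flag >
  config file > default. The resolved configuration and package version
  are echoed into every `summary.json`, making outputs self-describing.
* **Coordinates** are 0-based (x, y) = (column, row) with pixel centres
  at integers, one convention across ROI polygons, masks and centroids.

## Problem sizes used by the test suite

The suite exercises the full pipeline on scenes of 40–220 nuclei on
tiles of 384²–2048² pixels at 0.121 µm/px — large enough that
segmentation, watershed splitting, doublet/cluster handling and the
stage-to-stage bookkeeping are all active, while a full run of the suite
stays in the tens of seconds. The diploid 220-nucleus scene (seed 42) is
the reference "normal tissue" check: the pipeline must recover a ratio
within ±0.1 of 1.0 and both copy-number means within ±0.2 of 2.0. The
margin-of-error scaling law is checked on 50–5000 iid per-cell draws.

## Known limitations

* The classical segmenter is not a learned nucleus detector; heavily
  touching or textured nuclei on real slides will need parameter tuning
  and may still under-split (the >150 µm² gate then removes the worst
  merges, at the cost of those cells).
* The size gate is the only cancer-versus-stroma discriminator;
  morphology-based classification is out of scope.
* Silver chromogen detection by luminance/chroma can, in principle,
  confuse very dense hematoxylin chromatin with faint silver; the two
  soft thresholds are the knobs to separate them on a given assay.
* Only the 2023 ASCO/CAP breast rules and the IHC 2+ status mapping are
  implemented; gastric and endometrial rule sets are not.
* Whole-slide formats are not read; users export ROI tiles to TIFF/PNG.
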
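---
title: "Methods: high-throughput myofibroblast screening on synthetic plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-throughput myofibroblast screening on synthetic plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`myoscreen` implements the computational core of two high-throughput
screens for inhibitors of TGF-β1-driven fibroblast-to-myofibroblast
transition in primary lung fibroblasts, exercised end to end on synthetic
plates with known ground truth:

* **HCA** — a high-content imaging assay: nuclei are detected in the DAPI
  channel, cells are segmented by seeded propagation from the nuclei,
  ~90 per-cell features are extracted from the α-SMA and fibronectin
  channels, a linear support-vector classifier is trained on the
  in-plate controls and every cell on the plate is classified; the
  per-well myofibroblast fraction is rescaled to a control-anchored
  percent effect.
* **IPQA** — an impedance (real-time cell analysis) assay multiplexed
  with MRM protein quantification: traces are normalized to the
  compound-addition time point and baseline subtracted, responses are
  read at fixed time points, and α-SMA/COL1 peak areas are normalized to
  tubulin via surrogate tryptic peptides whose precursor and fragment
  m/z the package computes from monoisotopic residue masses.

Around these sit the screening statistics: a three-parameter logistic
(3PL) potency fitter with censoring, the Z′ screening-window
coefficient, Spearman rank correlation with exact permutation p-values,
and the hit-triage logic of a primary screen with viability filtering,
concentration-response confirmation and a reversal
(de-differentiation) protocol.

Wet-lab steps (culture, staining, digestion chemistry, instrument
control) are out of scope; the synthetic generators stand where the
laboratory would.

# The classification model

## Control anchoring

Each plate carries negative controls (5 ng/ml TGF-β1, no compound — the
0 % compound-effect condition, essentially pure myofibroblasts) and
positive controls (no TGF-β1 — pure fibroblasts).  Cells from these
wells, labelled by their well's condition, train a linear-kernel SVM on
standardized features (training mean/SD).  We fix the kernel to linear
because the assay's interpretability contract is a per-feature weight
ranking; the regularization constant defaults to 1.0 and is exposed but
not tuned — cross-validated accuracy, not the constant, is the quality
surface.  The majority control class is subsampled so training is
balanced; accuracy is estimated by stratified 10-fold cross-validation,
pooled over folds.

Control labels are condition labels, not cell labels: a few percent of
cells in a TGF-treated well genuinely remain fibroblasts, so CV accuracy
has a ceiling just below 1 even for a perfect decision rule.  This is a
property of the real assay as much as of the simulation.

## Percent effect

Per well, the classified myofibroblast fraction `f` is rescaled as

```
percent_effect = 100 * (f_neg - f) / (f_neg - f_pos)
```

with `f_neg`, `f_pos` the control-well mean fractions, so the TGF
control scores 0 and the untreated control 100.  The value is *not*
clipped to [0, 100] by default — over-normalized wells are informative —
and both the raw fraction and the percent effect are emitted, since the
two published scales (degree of differentiation vs compound effect) are
affine images of each other.

# Image features

All intensity work happens on background-corrected rasters: a white
top-hat with disc radius twice the largest granularity scale (32 px by
default), the standard parameter-free choice when the upstream pipeline
only says "background correction".

* **Granularity spectrum** — the percentage of total signal removed
  between successive grayscale openings with disc radii 1–8 px.  The
  sequence of openings is clamped to be pointwise monotone so every
  entry is ≥ 0 and the spectrum sums to ≤ 100 on any input.  This is
  the size-resolved texture descriptor that separates fibrillar α-SMA
  (myofibroblast stress fibers, signal removed at small radii) from
  diffuse staining.
* **Co-occurrence texture** — grey-level co-occurrence contrast,
  homogeneity, correlation, energy and entropy at offsets 1 and 3 px,
  four orientations pooled, on 32 levels.  Quantization is per cell
  (each cell's min–max range): texture must describe the arrangement of
  intensity *within* a cell, not the cell's brightness relative to its
  neighbours.  An earlier per-image quantization leaked a well-level
  covariate — one bright myofibroblast changed the texture coordinates
  of every fibroblast sharing the image — and broke held-out control
  anchoring; the per-cell scale removes that failure mode.
* **Intensity statistics** (mean, SD, MAD, quantiles, CV, skewness,
  kurtosis, integrated signal, bright-pixel fraction), **radial
  distribution** of signal in three concentric zones around the
  nucleus, and **shape** (area, perimeter, form factor, axis lengths,
  eccentricity, solidity, extent, nucleus/cell ratio).

That is ~40 features per marker channel plus shape — of the order of
100 rather than the >400 of a full profiling pipeline.  The fidelity
criterion is the classifier contract (control separability), not the
feature count.

Segmentation: Gaussian smoothing (σ = 2 px), Otsu threshold, and a
distance-transform watershed for nuclei (minimum area 30 px²); cells by
Voronoi-style seeded propagation of the whole-cell channel restricted to
its Otsu foreground.  Every nucleus yields exactly one cell region, so
cell count equals nucleus count by construction.  Cells touching the
raster border are kept by default (droppable via
`feature_config(drop_edge_cells = TRUE)`).  Where the published
description is ambiguous about whether marker features are computed on
sub-cellular marker regions or on the full cell mask mapped to its
nucleus, we use the full cell mask.

# Impedance processing

Raw cell-index traces are **divided** by their value at the reference
time (compound addition), the real-time-cell-analysis convention that
makes the normalized trace exactly 1 there; subtraction is available as
an option since "normalized to the time point" does not by itself fix
the arithmetic.  The identically normalized mean trace of baseline wells
(vehicle, no TGF-β1) is then subtracted.  Readouts are linear
interpolations at fixed times — 20 h after TGF-β1 addition for the
standard assay, 72 h for the reversal assay — with no smoothing (noise
is handled by replicates, not filters).  Normalization is idempotent,
and a nadir finder (earliest minimum in a window) supports the
relaxation phenotype of cytoskeleton-active compounds, whose synthetic
counterpart peaks at the relaxation time constant (2.5 h by default,
within the observed 2–3 h window).

# MRM chemistry

Precursor m/z is `(Σ monoisotopic residue masses + water + z·proton)/z`
with proton mass 1.007276 Th; y-ions carry the C-terminal residues plus
water, b-ions the N-terminal residues.  Carbamidomethylation (+57.02146
per cysteine) is available as a fixed modification but off by default —
none of the three surrogate peptides (GVVGLPGQR/COL1A1,
GYSFVTTAER/ACTA, DVNAAIATIK/TBA1A) contains cysteine.  The transition
table reports computed values to 2 decimals and carries the
instrument-tuned settings as annotation; where a tuned setting departs
from the monoisotopic calculation by more than 0.05 Th the row is
flagged rather than reverse-engineered.  Tests verify the calculator
against an independent oracle that rebuilds residue masses from
elemental compositions, plus the b/y complementarity identity
`b_i + y_(L−i) = M + 2·proton`.

# Dose–response statistics

The potency model is the three-parameter logistic

```
Y = Bottom + (Top - Bottom) / (1 + 10^(LogEC50 - X))
```

with `X` in log10 concentration.  Fitting is unweighted least squares
(Levenberg–Marquardt, Nelder–Mead fallback) with deterministic
self-starts: Bottom/Top from the dose-averaged responses at the extreme
concentrations, LogEC50 from the half-maximal crossing of a linear
interpolation of the dose means.  Bottom and Top are unconstrained by
default (anchoring them to controls is a caller-side choice).
Zero-concentration wells are excluded from the fit — they anchor the
percent scale upstream.  A fitted LogEC50 outside the tested range, or a
flat response, yields a *censored* result (`above_max`/`below_min`)
rather than an error; replicate summaries average uncensored EC50s on
the linear scale (mean ± SD, SD only for n ≥ 2) and propagate an
explicit `"> cmax"` bound when every replicate is censored.  For
downstream rank statistics censored potencies enter at their bound,
flagged, with a sensitivity path that excludes them — the published
correlation tables are not exactly recoverable from rounded, censored
summaries, so the package reports its own correlations under a stated
convention instead of targeting printed coefficients.

Recovery behaviour, measured by the test suite: exact (1e-6 in LogEC50)
on noiseless model data; with 10 % CV per well, 8 concentrations and 8
replicate wells per concentration — the assay's plating for
concentration–response experiments — the median EC50 error is ~6 %.
With single wells per concentration the least-squares optimum itself
(confirmed by a dense grid-search oracle) has ~16 % median error; the
replication, not the optimizer, is what buys the precision.

Assay quality uses the standard screening-window coefficient
`Z' = 1 - 3(σ_pos + σ_neg)/|μ_pos - μ_neg|` with sample SDs (n−1), and
Spearman correlations are rank-Pearson with average ties, exact
permutation p for n ≤ 9 (full enumeration) and the t approximation
above.

# The synthetic generators

The generators define the study conditions; their defaults are fixed
once and shared across assays so image-based and protein-based ground
truths agree.

* **Differentiation fraction.**  A well's expected myofibroblast
  fraction is `f_min + (f_max − f_min) · Hill(dose; 0.07 ng/ml, slope 2)
  · (1 − E)`, with `f_min = 0.005`, `f_max = 0.995` and `E` the
  compound's fractional inhibition `efficacy · conc/(conc + IC50)`
  (unit slope, so a fully efficacious compound at its IC50 removes
  exactly half the signal — the midpoint the 3PL fitter recovers).  The
  EC50 is shared with the α-SMA protein induction; the slope-2 dose
  rule reflects the steep differentiation response of the cells while
  keeping the stimulated control near-completely differentiated, which
  is what the ">97 %" training-accuracy regime presupposes.  Well-to-well
  variability is a truncated Gaussian on the fraction scale (SD 0.025,
  i.e. 2.5 percent-effect units on the control-anchored scale).
* **Cell rendering.**  Elliptical cells (fibroblast major axis 8 px,
  myofibroblast 12 px), nuclei as 3.8 px discs in DAPI.  Myofibroblasts
  carry 6 oriented stress-fiber segments in α-SMA and punctate fibrils
  in FN; fibroblasts are diffuse.  Each cell's in-mask mean is rescaled
  to its class mean times a lognormal factor (CV 0.15), so the
  configured 3-fold α-SMA contrast is reproduced by direct averaging
  over ground-truth masks.  Noise is Gaussian shot noise (variance ∝
  intensity, gain 4) plus read noise (SD 30 counts) on a flat
  300-count background; no optics/PSF simulation by design.
  Coordinates are 0-based, origin top-left; masks are label rasters.
  The in-paper description gives no distribution for cell-level
  variability, so these are the package's own choices of what a
  screening field plausibly looks like — passing tests demonstrate that
  the pipeline recovers engineered contrasts of realistic size, not
  that it would perform identically on any particular instrument's
  data.
* **Impedance kinetics.**  `raw(t) = CI₀·(1 + A·pulse(t) − relax(t)) +
  AR(1)`, where `pulse` is an exponential rise (τ = 6 h) times a
  sigmoidal decline centred at 24 h (the contraction/detachment of the
  differentiating layer), `A` is a Hill function of TGF dose (EC50
  0.5 ng/ml) scaled by compound inhibition, and `relax` is a gamma-like
  immediate drop peaking at 2.5 h, off by default and enabled for
  relaxant phenotypes.  AR(1) noise: SD 0.02, correlation 0.8.
* **MRM areas.**  Tubulin area ∝ cell number × lognormal (CV 0.10);
  ACTA and COL1 ratios follow `1 + (3 − 1)·Hill(dose; EC50)` with EC50
  0.07 and 0.05 ng/ml (unit slope, so noiseless dose series refit to
  their generating EC50 exactly), times compound attenuation and
  lognormal ratio noise (CV 0.08).
* **Compound libraries.**  `round(n · frac_active)` true actives with
  log-uniform IC50s, efficacies uniform in [0.85, 1]; an independent
  5 % of compounds is cytotoxic with its own log-uniform toxicity EC50.
  Active compounds also revert established myofibroblasts (reversal
  IC50 = prevention IC50 by default).  Toxicity being independent of
  activity means a toxic active is *correctly* rejected by the
  viability filter; screen recall is therefore assessed over non-toxic
  actives, with the toxicity flags themselves tested separately.
* **Seeds.**  One master seed per plate, split per well and stage by a
  31-bit rolling hash (`derive_seed`), so plates are bit-reproducible
  and wells independently regenerable.

## Reversal (de-differentiation) mode

TGF-β1 for 24 h, washout, compound for 72 h, readouts at 96 h (72 h for
impedance).  The generator gives the differentiated state persistence:
without a reverser the fraction stays at its TGF-established level
(vehicle wells score ≈ 0 % effect), and reversers pull it back toward
the untreated baseline through their reversal IC50.

# Problem sizes and numerical choices

The analyses run at desk scale: the default synthetic 384-well plate
carries 32 control wells per role with 40–80 cells imaged per well
(thousands of cells per class — the wet assay seeds 750 cells per well,
of which an imaging field captures a subset); screens use 200 compounds
with 20 actives; concentration–response experiments use 8
concentrations × 8 replicate wells.  The biological potencies of real
compounds are not reproducible without cells, so the quantitative
acceptance surface is the chemistry (exact m/z), the classifier and
assay-quality statistics on the default plate, and round-trip recovery
of programmed ground truth.

Numerical details worth knowing: EBImage grayscale morphology operates
on [0, 1] data, so all rasters are scaled by 1/65535 around
morphological calls; granularity openings are clamped pointwise
monotone; nadir and weight-ranking ties break deterministically
(earliest time, alphabetical feature); SVM decision values are oriented
so positive always means myofibroblast; flat dose-responses censor
rather than fail; degenerate controls (equal means) raise errors
everywhere a percent scale would divide by zero.

# Known limitations

* The renderer makes no attempt at optical realism (no PSF, no
  aberrations, no autofluorescence structure); classifier accuracies on
  these images bound what segmentation+features+SVM can do on cleanly
  resolved cells, not instrument performance.
* Viability is a scalar per-well readout (toxicity-scaled), not a
  modelled luminescence assay.
* Feature count (~90) is deliberately below a full >400-feature
  profiling pipeline; feature families, not identities, are
  reproduced.
* The exact convention behind the published cross-readout correlation
  coefficients is not recoverable from rounded, censored potency
  tables; the package states its own convention (bounds included,
  flagged, with an exclusion sensitivity path) and reports what it
  computes.
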
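---
title: "Linking NfL compartments to histological axonal damage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking NfL compartments to histological axonal damage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nflaxon)
```

## The scientific problem

Vasculitic neuropathy — ischaemic nerve damage from inflamed
nerve-supplying vessels — is hard to diagnose and to monitor. Neurofilament
light chain (NfL), a neuron-specific cytoskeletal protein released into
blood and CSF on axonal injury, is a candidate blood biomarker, but its
link to what is actually happening in the nerve has to be established
against the diagnostic gold standard: the sural nerve biopsy.

`nflaxon` implements the full analysis chain for such a
cross-compartmental study. Per patient it takes

* an NfL panel — serum, CSF and nerve-tissue concentrations (pg/mL) plus
  the tissue aliquot's total protein (mg/mL), and
* calibrated brightfield micrographs of four preparations: NF70-stained
  (neurofilament, DAB brown), CD68-stained (macrophages, DAB brown),
  methylene-blue semithin sections, and teased single-fibre strips,

and produces per-patient measures of **acute axonal degeneration**
(degenerating-fibre density, teased-fibre ovoid fraction, CD68+ area — all
percent-of-maximum normalised and averaged into a composite score) and
**chronic axonal loss** (NF70+ percent of fascicular area and
myelinated-fibre density, deliberately kept as two separate parameters
because they capture different aspects of loss). These are correlated with
the NfL panel by Spearman rank correlation, with the standard confounder
devices: detection-limit capping with a sensitivity analysis, the
serum/CSF ratio to discount central release, age-specific Z-scores, and a
secondary analysis restricted to patients without CNS disease.

Because no patient images or biosamples ship with the package, two
synthetic generators make every stage testable: a cohort simulator with
known latent damage levels, and slide renderers whose ground truth is
recorded from the painted pixel masks.

## Image quantification chains

### Colour deconvolution

Brightfield stains act as optical-density (OD) absorbers. A pixel's OD
vector is `-log10(I / 255)` per channel; with unit OD vectors for
haematoxylin and DAB (the Ruifrok–Johnston H-DAB constants, exposed via
`stainVectorsHDAB()`) plus their orthogonal residual, unmixing is the 3×3
matrix inverse applied per pixel, with negative concentrations clipped to
zero. The renderers composite through the *same* model, and a test asserts
that a pure-chromogen pixel unmixes with ≥ 95 % of its OD in the chromogen
channel.

### NF70 percent area (chronic loss)

DAB channel → Laplacian-of-Gaussian sharpening → Otsu threshold computed
from within-ROI pixels → 8-connected components → inclusive size gate
20–30 000 µm² → stained area as percent of fascicular area, per fascicle
and pooled.

Numerical choices that matter:

* **LoG scale and weight.** `logSigma = 2` px; the sharpened image is
  `dab − w·(LoG ∗ dab)` with `w = 0.25`. A small weight keeps flat stained
  plateaus nearly uniform after sharpening, so the histogram threshold
  falls in the wide empty gap between background and foreground rather
  than inside a spread-out foreground mode; with `w = 1` the LoG response
  across small blobs spans a wide value range and Otsu can shave boundary
  pixels off objects sitting exactly at the 20 µm² gate.
* **Within-ROI thresholds.** Otsu/Yen statistics use only pixels inside
  the fascicle ROI union; tissue outside fascicles would bias the
  histogram. Ties in the criterion resolve to the lowest bin.
* **Minimum-OD floor.** The threshold is `max(otsu, minOD)` with
  `minOD = 0.1`. On a blank or near-blank section plus sensor noise, a
  histogram criterion will happily split the noise distribution and report
  spurious area; the floor (chosen from the stain model: unmixed
  background stays ≲ 0.05 OD, chromogen ≈ 0.85 OD) makes "no staining"
  read as 0 %. A fully degenerate (single-intensity) ROI returns 0 % with
  a warning instead.
* **Size gate.** Component pixel areas are converted to µm² via the
  calibration; bounds are inclusive, so a 20 µm² object counts fully and a
  10 µm² or 35 000 µm² object contributes nothing.

### CD68 percent area (macrophage infiltration)

DAB channel → rolling-ball background subtraction → Yen threshold within
the ROI union → one 3×3 median pass on the binary mask (despeckle) → area
fraction. The rolling ball is implemented as grayscale morphological
opening with a disc element on a downsampled copy (the classic
large-radius strategy; default radius 50 px, 24 px at the small pipeline
scale). On a binary mask the 3×3 median equals a 9-neighbourhood majority
vote, which is how it is computed. Transverse and longitudinal sections
are quantified separately, normalised to the dataset maximum
(`normalizeToDatasetMax()`, maximum maps to 100) and averaged
(`combineOrientations()`; a patient with one orientation passes it
through).

### Semithin morphometry

Healthy myelinated fibres appear as dark myelin annuli around a pale
axoplasm lumen; fibres in acute (Wallerian-type) degeneration collapse
into filled grey-violet profiles. The detector thresholds the darkness
channel (Otsu over within-ROI pixels), fills enclosed lumina, labels
8-connected components, and gates candidates by circularity (≥ 0.6) and
equivalent outer diameter (2–20 µm inclusive). The lumen fraction
`lumen_area / outer_area` classifies each fibre: strictly below 0.10 →
degenerating, otherwise healthy. The strict inequality is the conservative
tie-break — a profile exactly at the threshold counts as healthy,
mirroring the convention that only unambiguous profiles are called
degenerating — and makes the degenerating count non-increasing as the
threshold is lowered. The published supervised-learning fibre detector is
deliberately not reproduced (no trained weights are available); this
classical detector has the same output contract, a count per fascicular
area. Fascicles flagged unusable are excluded from both numerator and
denominator of the densities.

### Teased-fibre ovoid fraction

Fibres are traced as horizontal bands in the row-mean darkness profile. A
fibre is *assessable* when its longitudinal presence profile covers at
least 90 % of the strip width (the operational definition adopted here for
"assessable"); it *has ovoids* when the profile drops below a
background-referenced threshold in at least two distinct gaps of ≥ 2
columns — fragmentation of the myelin into bead-like ovoids. Fewer than 20
assessable fibres triggers a warning (observed per-case counts range
20–53), zero is an error.

## Composite scoring

The three acute parameters are put on a common percent-of-maximum scale
(maxima computed over patients with non-missing values) and averaged.
Teased-fibre preparations exist only for a subset of patients, so the
ovoid component is optional: patients without it receive the mean of the
remaining two components, with `n_components` recorded; fewer than two
components yields no score. This averaging-of-available rule is the
package's reading of how a composite can cover more patients than the
teased subset; it keeps the score bounded by its component extremes and
invariant under rescaling any raw component (max-normalisation
invariance). Chronic parameters are never composited.

## NfL derivations

* **Capping.** CSF values above 25 000 pg/mL and tissue values above
  7 800 pg/mL (the maximum validated detection limits) are replaced by the
  limit and flagged; capping is idempotent.
* **Tissue percent of protein.** `nfl / (protein × 1e9) × 100` converts
  pg/mL against mg/mL to a percentage of total protein; both the raw
  concentration and this normalised value are carried through.
* **Serum/CSF ratio.** Discounts central NfL release. When the CSF value
  was capped, the true ratio can only be smaller, so the ratio carries a
  lower-bound-uncertain flag, and `cappingSensitivity()` re-runs any
  downstream analysis with capped values inflated by multipliers (default
  1, 1.5, 2, 5); multiplier 1 reproduces the primary analysis exactly.
* **Age Z-scores.** `Z = (ln serum − mu(age)) / sigma(age)` on the natural
  log scale (serum NfL is right-skewed). The packaged `referenceModel()`
  is an explicitly synthetic stand-in — log-linear mean
  `ln 8 + 0.025 (age − 20)`, constant SD 0.5, support 18–100 years — and is
  pluggable; clinical use requires parameters from a validated reference
  population.

## Correlation analysis

`spearmanCorrelation()` uses average ranks for ties, the Fisher-z 95 % CI
with standard error `1/sqrt(n − 3)` (the common software default whose
bracketed intervals clinical papers print; an approximation under ties),
and a two-tailed p from the t approximation with `n − 2` df, with an exact
permutation option (`pMethod = "exact"`, n ≤ 10, delegated to
`stats::cor.test`). `|r| ≥ 0.5` flags a moderately strong correlation.
`runPanel()` crosses {serum NfL, tissue NfL, serum/CSF ratio, serum
Z-score} with {acute composite, NF70 % area, fibre density} on all
patients and on the subgroup without CNS disease. Patients with *unclear*
CNS status are retained in that subgroup by default
(`cnsRule = "exclude_yes_only"`): only the nine patients with clearly
relevant CNS disease are removed, which is consistent with the restricted
sample sizes such a cohort produces; the stricter rule is available.
No multiple-testing correction is applied, matching the descriptive
character of the panel.

## What the synthetic data emulate — and what they do not

`simulateCohort()` draws latent acute and chronic damage levels (uniform
marginals, optionally correlated via a Gaussian copula — real cohorts
confound them, the default keeps them independent) and generates
log-normal NfL:

```
serum  = exp(ln baselineSerum + betaAge (age − 50) + betaAcute · acute + eps)
csf    = exp(ln baselineCsf  + betaAge (age − 50) + 0.3 · betaAcute · acute
             + betaCns · cns + eps)
tissue = exp(ln baselineTissue + betaAcute · acute + eps)
```

Defaults mirror the cohort-level study conditions: n = 35, ages 26–82,
`betaAcute = 1.5`, `sigmaNoise = 0.4`, P(CNS disease) = 9/35, teased-fibre
subset 14/35. The log-normal form matches the non-normal serum NfL
distributions that motivate rank statistics. Choices without a published
value are the package's own and flagged here: the serum↔tissue coupling
through the shared acute latent (no quantitative coupling is published),
the CSF share of the acute effect (0.3 — peripheral breakdown raises serum
far more than CSF, so the serum/CSF ratio retains most of the peripheral
signal), baselines of 10 / 600 / 500 pg/mL, and the age slope 0.02 per
year on the log scale.

`groundTruthHistologyTargets()` maps the latents linearly onto the five
read-outs: healthy fibre density 5000/mm² (low-mid of reported sural-nerve
morphometry — these are biopsied neuropathy patients) falling by up to
80 % with chronic loss, NF70 area 25 % falling likewise, degenerating
fibres up to 800/mm², CD68 up to 8 %, ovoid fraction up to 0.9 with acute
degeneration.

The renderers emulate: the H-DAB stain model with sensor noise (SD 3 grey
levels) and a mild illumination gradient; exact-area chromogen blobs
(truth equals request, so acceptance bands test the measurement chain, not
the renderer); non-overlapping annuli/filled profiles with outer diameters
clamped to ≥ 3 px so pixelated myelin rings cannot break; teased strips
whose ovoid gaps total < 10 % of the width so ovoid fibres stay
assessable. They do **not** emulate: stain variability and uneven
chromogen uptake, out-of-focus blur, tissue folds and edge artefacts,
overlapping or longitudinally sectioned fibres, fascicle-to-fascicle
heterogeneity, or scanner compression. Passing tests therefore demonstrate
the correctness of the measurement chain under its stated model, not
robustness to every real-world artefact; on real slides the parameters
(stain vectors, thresholds floors, gates) are the knobs to revisit.

## Pipeline, determinism and problem sizes

`runPipeline()` composes everything: simulate → render (NF70, CD68 × 2
orientations, semithin, teased subset) → segment/measure → score → derive
→ correlate → report. A single seed governs the run; re-running with the
same configuration is byte-identical for all CSV outputs, each of which
carries the package version, seed and a configuration hash in a header
line. Rendered slides in the pipeline are 96 × 96 px at 1 µm/px (fascicle
≈ 0.005 mm²), the package's chosen balance between morphological realism
and the cost of the replicated recovery studies; the per-patient expected
fibre count is Poisson-drawn from the target density and capped at the
packing feasibility of the fascicle, with a bounded thinning retry if
random sequential placement jams. Section-to-section biological
variability is a log-normal factor with CV 0.12 on the rendered targets.

Validation at larger scale (240 × 320 px semithin sections, 192 × 192 px
IHC slides) lives in the test suite: segmentation recovers rendered truth
exactly on noiseless input, within a few percent under default noise, and
the 200-replicate pipeline study recovers a positive acute-composite ↔
serum-NfL rank correlation essentially always while the uncoupled chronic
parameters stay centred on zero.

## Known limitations

* The fibre detector and ovoid rule are deterministic stand-ins for
  manual/learned procedures; their agreement with human raters on real
  material is untested here.
* The Fisher-z CI and t-approximate p are approximations under ties;
  exact inference is provided only for n ≤ 10.
* The age reference model is synthetic; Z-scores from it are not
  clinically interpretable.
* GeoJSON ROIs use pixel coordinates, not a georeferenced CRS; whole-slide
  pyramid formats are out of scope.
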
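# nflaxon

Cross-compartmental analysis of neurofilament light chain (NfL) and
histological axonal damage in sural nerve biopsies.

## What this package is for

Vasculitic neuropathy — nerve damage from inflammation of nerve-supplying
blood vessels — is difficult to diagnose and monitor. NfL, a
neuron-specific cytoskeletal protein released into blood and CSF when
axons break down, is a candidate biomarker, but its value depends on what
it actually tracks inside the nerve. `nflaxon` implements the complete
analysis chain for studies that put serum/CSF/tissue NfL panels side by
side with quantitative histology of the biopsied nerve, for
neuropathologists and biomarker researchers who want that chain
reproducible and testable end to end.

Per patient the package quantifies:

* **Acute axonal degeneration** — three read-outs combined into a
  percent-of-maximum composite score:
  1. density of degenerating fibres in methylene-blue semithin sections
     (dark-ring detector: threshold → fill lumina → 8-connected
     components → circularity/diameter gates; lumen fraction < 0.10 ⇒
     degenerating),
  2. fraction of teased fibres with ovoid formations (fragmentation gaps
     in the longitudinal intensity profile),
  3. CD68⁺ macrophage area (colour deconvolution → rolling-ball background
     subtraction → Yen threshold → despeckle), %max-normalised and averaged
     over transverse and longitudinal sections.
* **Chronic axonal loss** — two parameters kept deliberately separate:
  NF70⁺ percent of fascicular area (colour deconvolution →
  Laplacian-of-Gaussian enhancement → Otsu threshold → 20–30 000 µm² size
  gate) and myelinated-fibre density.
* **NfL derivations** — detection-limit capping (CSF 25 000 pg/mL, tissue
  7 800 pg/mL) with a multiplier sensitivity analysis, tissue NfL as % of
  total protein, the serum/CSF ratio (discounting central release), and
  age-specific Z-scores `Z = (ln sNfL − µ(age)) / σ(age)`.

These feed a Spearman rank-correlation panel
(r, Fisher-z 95 % CI, two-tailed p, n; `|r| ≥ 0.5` flagged as moderately
strong), run on all patients and restricted to patients without CNS
disease.

Since no patient data ship with the package, a synthetic cohort generator
(log-normal NfL with age trend, acute-degeneration effect on serum,
CNS-disease effect on CSF) and stained-slide renderers with exact
construction-time ground truth make every stage verifiable; the methods
vignette (`vignettes/nfl-axonal-damage.Rmd`) documents all models,
defaults and their limits.

## Worked example

```r
library(nflaxon)

# 1. The packaged patient-characteristics table
tbl <- readCohortTable(system.file("extdata", "cohort_table1.csv",
                                   package = "nflaxon"))
summarizeCohort(tbl)
#> CohortSummary
#>   patients: 35 (23 m / 12 f)
#>   CNS disease: 9
#>   vasculitis (definite/probable): 10 (6 acute or subacute)
#>   other diagnoses: 25
#>   median days biosample to biopsy: 4

# 2. A rendered slide with known truth, quantified by the NF70 chain
r <- renderIhcSlide(10, "nf70_dab", seed = 1, imageSize = c(160, 160),
                    nFascicles = 1, noiseSd = 0, illumGradient = 0)
nf70AreaFraction(r$image, r$rois)
#> AreaFractionResult: pooled 10.002% over 1 fascicle(s), 3 object(s)
truthOverall(r$truth)$pct_area
#> [1] 10.00155

# 3. The full pipeline on a synthetic cohort at the study conditions
res <- runPipeline(pipelineConfig(seed = 7))
spearmanCorrelation(res$merged$acute_composite,
                    res$merged$serum_nfl_pg_ml)
#> r = 0.54 [0.25 to 0.74]; p = 0.00082; n = 35
```

The last number is the package's core readout: in a cohort whose serum
NfL was generated with a strong acute-degeneration effect
(`betaAcute = 1.5` on the log scale), the acute composite score measured
from rendered slides recovers a moderately strong positive rank
correlation with serum NfL — while the chronic parameters, uncoupled from
NfL in the generator, stay near zero (see `res$panel` for the full 24-cell
battery).

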
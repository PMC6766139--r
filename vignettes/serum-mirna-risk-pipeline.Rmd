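---
title: "Serum miRNA biomarker discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum miRNA biomarker discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sermir)
```

## The problem

Circulating microRNAs are stable in serum and can be quantified by
RT-qPCR, which makes them attractive minimally invasive biomarkers for
tumours — here, for discriminating thyroid carcinomas and benign thyroid
nodules from healthy controls, and the aggressive medullary carcinoma
(MTC) from both. A typical discovery design is multiphase: a pooled-serum
array screen over hundreds of assays nominates candidates; a training set
of individual samples confirms them by per-miRNA tests; a validation set
re-tests the survivors; and the combined set is used for diagnostic (ROC)
evaluation. `sermir` implements every computational stage of that design,
plus a CT-level data generator, so the whole pipeline can be exercised and
tested end to end without access to patient samples.

## Relative quantification

qPCR reports the threshold cycle CT; each PCR cycle doubles the product,
so CT differences are log2 abundance ratios (amplification efficiency is
assumed to be exactly 2; no efficiency correction or inter-plate
calibration is attempted). Quantities:

* composite reference: the mean CT of the endogenous controls let-7d,
  let-7g and let-7i, a combination chosen for its stability in serum.
  Averaging CTs equals taking the geometric mean of the controls' linear
  abundances. The combining rule is a package convention; with arithmetic
  means it does not matter whether one subtracts each reference and
  averages the ΔCTs or averages first and subtracts once.
* ΔCT = CT(target) − CT(reference composite); relative expression =
  2^−ΔCT.
* pooled fold change = 2^−ΔΔCT with ΔΔCT the difference of pool ΔCTs.

Two structural laws follow and are enforced by property tests: one extra
ΔCT cycle exactly halves expression, and adding any constant to all of a
sample's CTs (an input-amount shift) leaves every ΔCT unchanged.

Samples missing one or two reference assays are normalized on the
remaining ones and flagged as degraded; samples missing all three cannot
be normalized and are dropped with a warning. A censored target CT yields
missing expression — it is never imputed as the cycle limit; prevalence of
censoring is instead handled by the Cq exclusion rule below.

## Candidate screening on pools

Equal serum volumes pooled per group emulate the array screen. Because
mixing equal volumes mixes molecules, the generator pools *linear*
abundances (mean of members' 2^−ΔCT), not CT values. An assay is a
candidate when all of the following hold:

1. raw case-pool CT strictly below 28 cycles (reliably quantifiable);
2. fold change of magnitude at least 5 (inclusive) versus *either*
   comparator pool, in *either* direction — `max(FC, 1/FC) ≥ 5`, since
   down-regulated markers are as useful as up-regulated ones;
3. optional membership of a user-supplied whitelist standing in for
   literature curation; with no whitelist the criterion is disabled.

Fold changes are computed on normalized pool ΔCT profiles; the pool's
internal control is configurable (designated references by default,
global-mean normalization as the alternative). Assays absent from every
comparator pool are reported `indeterminate` and never nominated.
Candidacy is monotone in both cutoffs, which the tests check.

## Group statistics

Per-miRNA summaries are mean ± SEM (SD/√n) of relative expression over
non-missing values. Comparisons use the pooled-variance two-sample
Student's t (df = nA + nB − 2), two-sided, because that is the test named
for this design; Welch's variant is available behind a flag for
sensitivity analysis. Demographic 2×2 tables use the Pearson chi-square
without continuity correction (Yates behind a flag). Tests run on the
2^−ΔCT scale to match the reporting units; a ΔCT-scale option exists
since the choice of testing scale is open — on lognormal data the ΔCT
scale is better powered, but we default to the reporting scale.

An assay is excluded when its Cq exceeds 35 cycles (or is censored) in
*strictly more than half* of the samples — "most samples" operationalized
as >50%, configurable. No multiple-testing correction is applied by
default, mirroring the design being modelled; `p.adjust`-based BH
correction can be applied by the user on the returned tables and is
deliberately not wired into the retention rule.

## The risk-score classifier

For marker *j* with case-vs-control direction d_j (fixed from training
group means before any weight fitting):

* threshold τ_j = 95th percentile of training-control expression if UP,
  5th percentile if DOWN, by linear interpolation between order
  statistics (position 1 + (n−1)p; `quantile` type 7). Fewer than 20
  controls triggers an instability warning.
* s_ij = 1 when sample *i* strictly exceeds τ_j (UP) or falls strictly
  below it (DOWN); ties score 0; missing expression scores 0 with a
  logged imputation count.
* weight W_j = slope of the univariate logistic regression of case status
  on s_j, which for a binary predictor is the log odds ratio. Fitting is
  by IRLS (`glm`, binomial, tight convergence); on a zero cell in the
  s×label table (separation) the Haldane–Anscombe correction (+0.5 to all
  cells) is applied and flagged; a constant s_j gets weight 0 and a
  DEGENERATE flag. Separation handling is a package addition: with
  15-sample MTC groups a zero cell is likely in practice.
* risk score RSF_i = Σ_j W_j s_ij, exactly.

One wording point deserves note: the natural-language description of the
down-regulated rule in this literature sometimes reads as "higher than the
lower 5% reference interval", which would score nearly every sample 1.
The only rule consistent with risk semantics scores a down-regulated
marker when expression falls *below* the 5th-percentile bound, and that is
the default; the literal reading remains selectable via
`down_rule = "above_lower"` for sensitivity analysis.

The model is frozen after training: `predict()` re-estimates nothing, so
validation data can never leak into thresholds or weights (tests
byte-compare the serialized model with and without validation samples
present). By construction about 5% of training controls exceed each
marker's interval; on large control sets this calibration is checked at
n = 10,000 within ±0.01.

## ROC evaluation

AUC is the tie-corrected concordance probability (Mann–Whitney), computed
from midranks and verified against brute-force pairwise counting. The
empirical curve uses the decision rule `score > threshold` at every
distinct score plus infinite endpoints, so its trapezoidal area equals the
pairwise AUC to 1e-12 (asserted at construction). Confidence intervals
are normal-approximation with either the DeLong placement-value variance
(default; tie-robust) or Hanley–McNeil (the classic SPSS-era
approximation), clipped to [0, 1]; a zero variance (perfect separation)
returns the degenerate point interval with a flag. Down-regulated markers
used directly as scores are auto-oriented so reported single-marker AUCs
are ≥ 0.5, with the flip recorded.

## The synthetic study generator

The generator emulates the data-generating setting the analysis assumes,
at the study's own conditions: group sizes 100 PTC / 91 benign / 15 MTC /
89 controls, training split 36/36/32, validation 64/55/57, a 756-assay
screening universe, pools of 20, and detection-limit censoring above 40
cycles. Per sample, a global input-amount shift (reference CT
~ N(26, 1.5)) is shared by all assays; per well, technical noise
(SD 0.15 cycles) is added; per marker and group, the ΔCT is normal —
equivalently expression is lognormal, the standard model for qPCR
abundance. The shipped effect sizes are the reported validation-set group
means of the six-miRNA panel, with coefficients of variation derived from
the reported SEMs (CV = SEM·√n / mean, giving CVs around 0.35–0.70); the
MTC group uses the means reported for the matched MTC comparison for the
three miRNAs assayed there and keeps the benign distribution for the
other three (a convention — those markers were never assayed in MTC).
Two low-abundance decoy assays (mean relative level 5·10⁻⁴, i.e. Cq ≈ 37)
exercise the Cq > 35 exclusion, and 23 null fillers bring the quantified
target count to 31, the size of a typical carried-forward candidate set.

Because expression is lognormal, a mean-correction term is applied so the
configured group means are *arithmetic* means of the generated
expression: ΔCT ~ N(−log2 m + (ln2/2)σ², σ²) has E[2^−ΔCT] = m, where σ²
is the variance of the *observed* ΔCT (biological plus technical noise,
including the averaged reference noise, σ² = σ_bio² + (4/3)σ_tech²).
Tests confirm convergence of generated means to configured means at
n = 5,000 within 2%, and exact recovery of planted fold changes in the
noise-free limit.

What the generator does not emulate: between-plate/run effects (a single
global reference-shift knob stands in for them), amplification-efficiency
variation, correlation between markers within a sample beyond the shared
input shift, and any real matching algorithm — MTC-arm "matched" subsets
are seeded draws with matched demographics generated directly. Passing
tests therefore demonstrate correctness of the pipeline's computations
and calibration under the assumed noise structure, not performance on
real serum panels.

## Pipeline orchestration

`run_pipeline()` executes screening → training → validation → combined
ROC → MTC arm with a frozen model between training and validation.
Training retention requires Student's t p < 0.05 in the designated
comparison (PTC vs control by default; requiring several comparisons is
configurable), after the Cq filter. The quantified cohort assays play the
role of the screened candidate set: at realistic panel effect sizes
(1.4–2.8-fold) the 5-fold pooled criterion is *not* met by the panel
markers — pooled screens nominate with optimism that individual-sample
phases do not reproduce, and the simulation preserves that honest gap
rather than forcing the stages to agree. The MTC arm reuses the frozen
normalization and ROC machinery on the up-regulated markers with
comparison-specific reference intervals (the "control" population is the
matched comparator group of each comparison).

Determinism is a contract: a config plus seed reproduces every simulated
CSV and written report byte for byte (no wall-clock timestamps enter any
artifact).

## Numerical and design choices

* Percentiles: `quantile` type 7 (1 + (n−1)p), the interpolation rule
  stated above; other definitions differ at these n by amounts that can
  flip single binarizations.
* Strict inequalities at all thresholds (CT < 28; expression > τ; Cq
  fraction > 0.5); inclusive fold-change cutoff (≥ 5).
* Zero-variance t-test inputs: equal means give t = 0, p = 1; unequal
  means with zero pooled variance are an error rather than ±∞.
* glm convergence epsilon 1e-12 so the slope matches the closed-form log
  odds ratio to better than 1e-6.
* Expected values in unit tests at the boundary of floating point (the
  halving law) are asserted at 1-ulp tolerance.

## Problem sizes used by the test suite

The suite exercises: 500 random ROC instances (n ≤ 50 per class) against
the brute-force oracle; 200 random logistic-weight tables (N ≤ 200); 2,000
null-study replicates for type-I calibration of training retention and
panel AUC; 100 full-pipeline seeds for panel recovery; 200 seeds each for
pooled-screen recovery and the MTC-arm AUC ordering; and n = 10,000
control sets for binarization calibration. These sizes keep Monte-Carlo
standard errors well inside the asserted tolerances.

## Known limitations

* The retention stage at the shipped training split (36 vs 32) has
  per-marker power well below 1 at the shipped effect sizes, so single
  runs frequently retain a proper subset of the panel; this is a property
  of the design being emulated, not of the implementation.
* Univariate weights only: no joint or penalized logistic model, by
  design.
* Empirical ROC only: no smoothing, partial AUC, or paired curve
  comparison tests.
* The generator's null fillers and decoys are deterministic conveniences,
  not a model of the full miRNome.
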
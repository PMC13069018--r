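---
title: "Methods: normalization, CDKPredX classification, and interaction testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization, CDKPredX classification, and interaction testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdkpredx)
```

This vignette is the package's own account of its methods: the models and
procedures it implements, the parameters that matter, the numerical
conventions fixed once and used everywhere, and what the synthetic cohorts
can and cannot tell you about real data.

## The scientific setting

In ER-positive, HER2-negative ("luminal") breast cancer, CDK4/6 inhibitors
combined with endocrine therapy and cytotoxic chemotherapy are competing
neoadjuvant options, and no established biomarker says which tumor should
receive which. The working hypothesis behind CDKPredX is biological: tumors
that are highly proliferative, strongly ER-driven, and immunologically cold
depend on the cyclin D–CDK4/6–Rb axis and should respond preferentially to
CDK4/6 blockade, while immunologically active, less ER-dependent tumors
respond better to chemotherapy. The package turns that hypothesis into a
reproducible pipeline: normalize expression, score three gene modules,
classify, and test whether treatment effect differs by class in a
randomized comparison.

## Expression preprocessing

Raw gene-level counts with gene lengths go through a fixed chain
(`normalize_expression()`):

1. **Low-count filter.** Genes with total raw counts ≤ 10 across all
   samples are removed (a gene summing to exactly 10 is removed). The
   filter is idempotent.
2. **Gene-length scaling.** Each gene's (possibly per-sample) length is
   divided by its geometric mean across samples and counts are divided by
   the normalized length. With one length per gene this is a no-op; it only
   acts when effective length varies between samples.
3. **TMM factors.** Between-sample scaling factors are the trimmed mean of
   M-values computed by `edgeR::calcNormFactors()`: reference library by
   75th-percentile count fraction closest to the mean of those; per-pair
   log-ratios (M) and mean abundances (A) on genes nonzero in both
   libraries; double trimming at 30% (M) and 5% (A); inverse
   asymptotic-binomial-variance weights; factors rescaled to geometric
   mean 1 (asserted to 1e-9). The test suite checks the factors against an
   independent direct evaluation of the published algorithm to 1e-6.
4. **TPM and log2.** TPM uses the TMM-effective library size (column sum ×
   factor), so TPM columns sum to 1e6/factor, and expression is
   `log2(TPM + 1)`. The pseudocount of 1 bounds values below by 0 and is
   the common choice for TPM; it is configurable.
5. **Sample QC.** Per-sample median Euclidean distance to all other samples
   over all retained genes; a sample is an outlier when its median distance
   strictly exceeds P75 + 3·IQR of the median distances. "Exceeding" is
   read as strictly greater, so a sample exactly at the threshold is kept,
   and a degenerate cohort of identical samples flags nobody.

Two numerical conventions are fixed package-wide: all quantiles (P25, P50,
P75, IQR) use linear interpolation between order statistics
(`stats::quantile` type 7), and stage order is filter → length scaling →
TMM → TPM → log2 → outlier QC.

**A deliberate nuance.** Uniformly rescaling one sample's counts leaves its
M/A values — and thus the composition the TMM factor estimates — unchanged,
so the depth change cancels exactly gene-wise (the TPM ratio is a
constant). It is *not* bit-identical, because the TMM precision weights
depend on absolute counts; the residual factor shift is ~1–2% on desk-scale
matrices and shrinks with gene count. The tests assert the exact
constant-ratio property plus a 0.1 log2-unit bound on the residual. An
unweighted trimmed mean would be exactly invariant, but the weighted form
is the published method and is kept.

## Metagene scoring and the CDKPredX rule

A metagene score is the unweighted arithmetic mean of log2 expression over
a gene set's members present in the matrix (`metagene_score()`). Scores are
only computed when at least `min_fraction_present = 0.5` of the set is
present — published signatures rarely map completely onto another
platform — and the missing genes are reported. The score is bounded by the
member-gene range per sample.

`cdkpredx()` scores the `Pr`, `Er`, `Im` modules and dichotomizes with
module-specific cohort quantiles: **lower quartile for Pr, median for Er
and Im**, ties high. The tie rule makes a median split at least 50% high
deterministically. The Q1 gate for Pr is read as *Pr high when ≥ Q1*
(~75% of samples high): proliferation is a permissive gate, and the
opposite reading (top quartile) would change the positive prevalence from
~18.75% to ~6%, inconsistent with a reported positive fraction near a
quarter of a cohort. Then

```
positive  <=>  pr_call = high  &  er_call = high  &  im_call = low
```

Every sample receives exactly one label. Raising a positive sample's Im
score above the Im median flips it negative; calls are invariant under any
strictly increasing transform of the per-sample scores (and under affine
transforms of the whole expression matrix — a *nonlinear* gene-level
transform does not commute with the metagene mean, so matrix-level
invariance is only affine).

**External cohorts.** `predict()` re-derives the same quantile levels
(0.25/0.5/0.5) within the new cohort by default, which makes labels
invariant to global shifts between platforms; an `absolute` mode transfers
the fitted log2 thresholds instead. Both are provided because "the same
cutoffs" is ambiguous between the two readings; re-derived quantiles are
the default as the only mode that is meaningful across platforms with
different dynamic ranges. Module gene lists ship as data (GMT), never
hard-coded: the generator's module lists are synthetic placeholders, and
users substitute published lists.

## Association statistics

- `reconstruct_counts()` inverts one-decimal printed percentages to integer
  counts, requiring `|100 r/n − rate| < 0.05`; with only a combined total
  it searches all splits and demands uniqueness, raising an ambiguity error
  listing the alternatives otherwise.
- `odds_ratio_wald()` uses the closed form `(ad)/(bc)` with
  `exp(log OR ± z·sqrt(1/a + 1/b + 1/c + 1/d))`; `z` is computed as
  `qnorm(0.975)`, not hard-coded. Zero cells error unless Haldane's +0.5 is
  requested explicitly.
- `fisher_exact()` wraps `stats::fisher.test` (two-sided hypergeometric
  summation).
- `logistic_interaction()` fits `endpoint ~ arm * biomarker` by ML on
  complete cases (listwise deletion, no imputation) and tests the
  interaction with a likelihood-ratio test, the primary method; the Wald
  test of the coefficient is reported alongside, and the two agree to about
  a decimal at trial scale. Stratum odds ratios come from stratum-specific
  logistic fits, which on a fully cross-classified 2×2×2 table equal the
  closed-form table odds ratios (checked to 1e-6). Arm×biomarker cells in
  which every subject has the same outcome make the MLE diverge; the
  function names the degenerate cells in an error instead of returning an
  unbounded fit. No multiplicity adjustment is applied to association
  p-values.
- Clinical metrics are direct formulas: CCCA is Ki67 ≤ 2.7% (boundary
  arrested), easTILs% = 100 × TIL cell area / stroma area (unit-invariant),
  and the SUVmax week-12/baseline ratio with relative decrease
  100 × (1 − ratio).

## Differential ranking and enrichment

The per-gene two-group statistic is a Welch (unequal-variance) t-test on
log2 expression with the fold change as the difference of group means. This
is a deliberate substitution: the ranking metric, thresholds, and GSEA
settings are the contract here, not the count-model fit, and a
location-test on log2 expression preserves the ranking semantics. The rank
score is `-log10(p) × sign(log2FC)` with zero p-values floored at the
smallest positive double; genes pass as differentially expressed when
`padj < 0.05` (Benjamini–Hochberg via `stats::p.adjust`) and
`|log2FC| > 0.5`, both strict.

`preranked_gsea()` implements the classical weighted Kolmogorov–Smirnov
running sum with weight exponent 1 on `|rank score|` (the cited tool's
default; the exponent is not stated by the protocol this follows, so the
convention is adopted and recorded here). The null is gene-label
permutation — the only null available from a pre-ranked list — with a
shared null per distinct set size; `NES = ES / mean(|null ES| of matching
sign)`, so null NES magnitudes center at 1 by construction; the permutation
p is two-tailed by sign with the +1 correction; BH across scored sets. Set
sizes are bounded to [10, 500] after intersection with the ranking (sets
outside the bounds are dropped; a set with no ranked genes at all is an
error). The enrichment-score statistic is cross-checked against
`fgsea::fgseaSimple` in the test suite; results are bit-reproducible for a
fixed seed (default 1000 permutations).

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the analysis assumes, not real
transcriptomes. Per sample, latent high/low states are drawn independently
for the three modules with marginal rates (0.75, 0.5, 0.5) — chosen to
mirror the classifier's Q1/median/median call rates — and the **true**
biomarker label applies the classification rule to these noise-free states.
Truth is therefore independent of cohort composition, an unambiguous
recovery target. Latent log2 expression is per-gene baseline (uniform on
[2, 8] log2 units) + module mean shift (default 2 log2 units) × state +
block-correlated Gaussian noise: within a module, noise splits into a
shared and an independent part so the gene–gene noise correlation equals
`within_module_correlation` (default 0.5). Counts are Poisson around
`2^latent × length/1000 × depth` with lengths uniform on [300, 5000] bases
and log-normal depths; Poisson suffices to exercise normalization, and
overdispersion is deliberately not layered on.

Arm assignment is Bernoulli(0.5) and the response is Bernoulli with
log-odds `b0 + b1·arm + b2·label + b3·arm·label`. The default coefficients
`(qlogis(0.656), log(0.40), qlogis(0.316) − qlogis(0.656), log(1.99/0.40))`
encode the study conditions: arm-by-subgroup response rates 47.8%/31.6% in
the biomarker-positive stratum and 43.3%/65.6% in the negative stratum,
i.e. within-stratum odds ratios 1.99 and 0.40 with a qualitative
interaction. The default cohort size is 163 (an analyzed-population scale)
with a 31-gene biomarker split (16, 4, 11) across Pr/Er/Im — the total is
what matters; the per-module split is not published, and only the 4-gene ER
module has a documented size, so the split is an explicit placeholder.
Secondary clinical fields (ORR24, pCR, RCB class, Ki67, SUVmax with
arm-specific week-12/baseline ratio means 0.40 vs 0.53) are generated at
plausible marginal levels for endpoint plumbing, not for biological
realism. All randomness flows from one integer seed; identical seeds give
bit-identical cohorts.

`inject_outliers()` adds a latent log2 shift to a random *fraction* of
genes (default half) of k samples and regenerates their counts. The
fraction matters: a shift on **all** genes is exactly a library-depth
change, which TPM normalization removes by design — such a sample is
invisible to distance-based QC on normalized expression, and correctly so.
A subset shift creates a compositional outlier the QC stage detects;
`gene_fraction = 1` reproduces the pure depth shift when that behavior is
wanted.

### What the synthetic cohorts do and do not show

Passing tests on synthetic cohorts demonstrate that the pipeline's
statistics behave as designed: TMM matches the published algorithm, the
classifier recovers a known latent subgroup near its 18.75% design
prevalence, stratum CI coverage is nominal, the interaction test keeps its
size, and enrichment p-values are uniform under the null. They do **not**
show that real tumors separate into these modules, that Poisson noise
captures RNA-seq overdispersion, or that the placeholder gene lists carry
the biology of the published modules; batch effects, full-transcriptome
covariance, and read-level artifacts are out of scope. One measured
coupling is worth knowing: after the count layer, TPM's shared library-size
denominator correlates the three module scores slightly, so the
*count-level* positive prevalence runs a little above the analytic 18.75%
(~21% at n = 2000); the independence premise holds exactly on the latent
scale, which is what the prevalence checks use.

## Problem sizes used in the checks

The test suite runs at desk scale, chosen as the smallest sizes at which
each property is statistically identifiable: TMM oracle equivalence on
200×6 matrices; prevalence, correlation, and coefficient recovery at
n = 2000; CI coverage and interaction type-I error over 500 cohorts of
n = 180 (matching a trial-scale randomization); enrichment calibration on
200 random sets at 1000 permutations. Trial-scale results that depend on
the controlled-access patient data (e.g. a specific cohort's positive
count or a signature correlation) are not reproducible from synthetic data
and are replaced by these property suites.

## Known limitations

- Single-sample (cohort-free) classification is intentionally absent: the
  thresholds are cohort quantiles.
- The per-gene count model behind differential ranking is a log-scale
  location test, not a negative-binomial fit; rankings agree in ordering
  for moderate-to-large groups but p-value magnitudes differ from count
  models.
- The generator's module gene lists are placeholders; substitute published
  lists via GMT for any real application.
- Interaction tests at trial scale are exploratory: the package follows the
  no-multiplicity-adjustment convention of forest-plot subgroup displays.
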
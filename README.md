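# cdkpredx

Translational analysis toolkit for two-arm neoadjuvant breast cancer trials
with baseline bulk RNA-seq. The package is built around a simple question:
*can a transcriptomic classifier identify the luminal tumors that respond to
CDK4/6 inhibition plus endocrine therapy but resist chemotherapy?* It
provides everything needed to ask that question reproducibly — from raw
count normalization through classification to the treatment-interaction
statistics — together with a synthetic-cohort generator with known ground
truth, so the whole chain is testable without access to patient-level trial
data.

## The model at the core

**CDKPredX** summarizes each tumor by three metagene scores, each the
unweighted mean of log2 expression over a gene module:

- `Pr` — proliferation (mitosis kinases),
- `Er` — estrogen-receptor signalling,
- `Im` — immune activity.

Each score is dichotomized at a cohort quantile: the **lower quartile** for
`Pr` (a permissive gate: ~75% of samples are Pr-high) and the **median** for
`Er` and `Im`, with ties called high. A sample is

```
CDKPredX+  <=>  Pr high  AND  Er high  AND  Im low
```

so under independent modules the expected positive prevalence is
0.75 × 0.5 × 0.5 = 18.75%. The classifier is "fitted" by deriving the three
thresholds from a cohort; applying it to an external cohort re-derives the
same quantile levels within that cohort (default) or transfers the absolute
thresholds.

The biomarker is evaluated against a randomized binary endpoint with a
logistic interaction model

```
logit P(response) = b0 + b1·arm + b2·biomarker + b3·arm·biomarker
```

where `b3` is tested with a two-sided likelihood-ratio test and each
stratum's arm odds ratio carries a Wald CI. Expression preprocessing follows
the standard bulk RNA-seq chain: low-count filtering (total counts ≤ 10),
gene-length geometric-mean scaling, TMM scaling factors, TPM on
TMM-effective library sizes, log2 transform, and median-Euclidean-distance
sample QC (flag if median distance > P75 + 3·IQR).

## Worked example

```r
library(cdkpredx)

# a trial-sized synthetic cohort with known truth
co  <- simulate_cohort(sim_config(n_samples = 163, n_genes = 1000, seed = 7))
nr  <- normalize_expression(co$counts, co$lengths)
qc  <- detect_outliers(nr$expression)
fit <- cdkpredx(nr$expression, co$gene_sets)
print(fit)
#> CDKPredX classification (cohort: derivation)
#>   samples: 163; positive: 30 (18.4%)
#>   thresholds: Pr >= 8.54 (Q1), Er >= 8.39 (median), Im < 9.88 (median)

cl <- co$clinical
cl$biomarker <- fit$label[cl$sample_id]
logistic_interaction(cl, "orr12", "arm", "biomarker")
#> Treatment x biomarker interaction (orr12 ~ B vs A x biomarker, n = 163)
#>   negative: OR = 0.463 (95% CI 0.231-0.929), p = 0.0301, n = 133
#>   positive: OR = 3.75 (95% CI 0.754-18.6), p = 0.106, n = 30
#>   interaction: p = 0.0146 (LRT; Wald p = 0.019)
```

The classifier recovers a positive subgroup near its 18.75% design
prevalence, and the refit finds the qualitative interaction the generator
encodes: the positive stratum's odds ratio favors the CDK4/6-inhibitor arm
(B) while the negative stratum favors chemotherapy (arm A).

Published summary tables can be analyzed directly. One-decimal response
rates plus group totals determine the integer counts:

```r
pos <- reconstruct_counts(c(47.8, 31.6), total = 42)   # 11/23 and 6/19
odds_ratio_wald(c(11, 12, 6, 13))
#> OR = 1.99 (95% CI 0.559-7.05), p = 0.288 [wald, n = 42]
```

`run_pipeline()` drives the full chain (simulate/load → normalize → QC →
classify → associate → GSEA) from one YAML config and writes a JSON manifest
with per-sample accounting.

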
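---
title: "Methods: methylation, mutation and expression biomarkers of hypomethylating-agent response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation, mutation and expression biomarkers of hypomethylating-agent response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## Scope

epiresist implements the biomarker analysis used to identify patients with
relapsed/refractory acute myeloid leukemia (r/r AML) who are unlikely to
respond to a hypomethylating agent (HMA): restriction-enzyme (DREAM)
methylation processing and CIMP-style clustering, a panel-variant filter
cascade and mutation summaries, a 7-gene qPCR expression panel with the
four-gene z4 resistance score, exact 2x2 association tests and
label-permutation differential methylation, and Kaplan-Meier / Cox /
logistic outcome models. A calibrated synthetic-cohort generator provides
the joint data structure the analysis assumes, so every stage is testable
without patient data.

## DREAM methylation processing

DREAM digests genomic DNA sequentially with two neoschizomers recognizing
CCCGGG. SmaI cuts only unmethylated sites, leaving blunt ends; XmaI is
methylation-insensitive and leaves a 5' CCGG overhang. Sequenced fragment
ends therefore start with `CCGGG` (methylated signature) or `GGG`
(unmethylated signature), and per-site methylation is the methylated
fraction of signature reads. `classify_read_signature()` implements exactly
this prefix rule; the chemistry fixes the encoding, and classification uses
the prefix only.

Downstream processing follows the conventional thresholds, all exposed as
arguments:

* `coverage_filter()` keeps sites covered with at least 20 reads
  (`min_reads`) in at least 75% of samples (`min_sample_frac`); entries
  below the read threshold become missing. Site order is preserved, and
  tightening `min_reads` can only shrink the retained set.
* `impute_pmm()` fills missing entries by predictive mean matching. The
  published form of PMM does not pin down the prediction model or donor
  count, so the package uses the simplest defensible model: a per-site
  linear regression of observed methylation on the sample-wise mean
  methylation (one regressor), with `n_donors = 5` donors and a uniform
  draw among them. Imputed values are always members of the site's
  observed values; a site with no (or fewer than `n_donors`) observed
  values is an error naming the site. When the regressor is constant the
  prediction falls back to the site mean.
* `hypervariable_sites()` selects sites with across-sample standard
  deviation strictly above `sd_threshold = 0.10` on the 0-1 fraction scale
  ("SD > 10%"), using the n - 1 denominator.
* `cluster_methylation()` runs Ward-linkage (`ward.D`) hierarchical
  clustering on Euclidean distances between samples, cut at `k = 3`. The
  cluster holding a strict majority of the normal-control samples is
  labeled *normal-like*; among the rest, the cluster with the highest mean
  methylation at CpG-island sites is *CIMP-like*, the others
  *intermediate*. If normals are absent or split with no majority, labels
  fall back to ordering clusters by mean CGI methylation and the result is
  flagged. Whether normal samples should contribute to the hypervariable
  SD is not settled; the package computes SDs over whatever samples are in
  the matrix, so the caller decides by inclusion.

## Panel variants

`filter_variants()` applies the cascade: depth >= 100 reads, variant
quality >= 50, variant allele fraction >= 5%, a COSMIC hematopoietic
annotation, and absence from common dbSNP (population frequency > 1%).
Pass/fail is order-independent; the rejection tally attributes each failing
call to the first failing rule in the listed order. The quality threshold
is compared on the variant-record quality field as supplied; no
recalibration is attempted. COSMIC/dbSNP membership is consumed as
pre-annotated columns rather than live database queries, which keeps the
analysis version-pinned and testable. FLT3-ITD, which amplicon panels
detect poorly, is expected as an externally supplied flag when available.

`build_mutation_matrix()` collapses passing calls to a binary gene x
patient matrix (idempotent under duplicate calls; patients without calls
are all-zero columns). `ras_status()` reports the KRAS | NRAS union plus
any patient carrying both — biologically unexpected, hence surfaced as an
exclusivity report instead of silently merged. `compare_frequencies()`
tests each gene against an external reference cohort with a two-sided
exact test at the Bonferroni-adjusted level `alpha / n_tests`
(0.05 / 19 ≈ 0.0026 for the conventional 19-gene myeloid comparison).

## Expression panel and the z4 score

Relative expression is `dCT = mean Ct(GAPDH) − mean Ct(target)` over qPCR
triplicates (higher dCT = higher expression); missing wells are dropped
from the average and fully missing triplicates flagged. Per-gene z-scores
standardize dCT across the analyzed cohort (n − 1 SD). The pooled cohort is
the default standardization frame because the combined-cohort analysis is
the primary one; `zscore_panel(by = "cohort")` supports the
discovery/validation split. Whether the original clustering used dCT or
standardized values is not stated; standardized values are used so that no
single high-variance assay dominates the Euclidean distance.

The resistance score is `z4 = zCDA + zP15 + zCTCF − zDNMT3B`; `z4 < 0`
predicts resistance and the boundary `z4 = 0` is assigned to the sensitive
side, matching the published partition of 38 vs 84 patients. Cluster
labeling in `cluster_expression()` follows the signature: R is the cluster
with higher mean zDNMT3B and lower mean zP15, DNMT3B deciding on conflict,
with a deterministic zCDA tiebreak (logged) for exact ties.

## Association statistics

`fisher_exact_2x2()` uses the minimum-likelihood two-sided convention: the
p-value sums hypergeometric point probabilities (margins fixed) that do
not exceed the observed table's probability, with a `1 + 1e-7` relative
guard for floating-point ties. This matches mainstream implementations and
is documented because the alternative (doubling the one-sided p) changes
borderline values. The odds ratio is the conditional MLE, with 0 and
infinity allowed. An empty margin returns p = 1 with a warning.

`permutation_dmc()` tests each site's absolute responder/non-responder
mean-methylation difference by permuting labels jointly across sites. The
statistic is the absolute mean difference — unnamed in the original
description, chosen as the simplest location statistic consistent with it.
When `choose(n, n1) <= 10000` all label arrangements are enumerated and
the p-value is exact; otherwise `B` random permutations are drawn and the
add-one estimator `(1 + #{>= observed}) / (1 + B)` keeps p away from zero.
"Site permutation" could also mean shuffling site positions; label
permutation was adopted because it preserves the per-site distribution and
directly targets the response association. Benjamini-Hochberg adjusted
p-values are returned alongside.

`discovery_validation()` intersects sites with p < 0.05 in both cohorts
(symmetric in its arguments); `feature_enrichment()` tests hit sites
against annotation flags (CGI, CTCF, enhancer, promoter) with exact 2x2
tests; `max_line1_demethylation()` is baseline minus the cycle-1 minimum,
floored at zero percentage points.

## Survival and response models

Kaplan-Meier estimation, the log-rank test, Cox partial likelihood (Efron
tie handling, Newton-Raphson to a 1e-9 tolerance) and binomial-GLM
logistic fits are delegated to the survival package and `stats::glm`,
behind the module's interface. The package contributes the contract
around them:

* *Backward elimination*: starting from all terms, the largest-p term is
  dropped while any Wald p >= 0.05 (the stay threshold is an argument; the
  original analysis states backward regression without one). The
  elimination trace is part of the report, and elimination is
  deterministic given the data.
* *Separation handling*: a binary predictor level with zero responders (or
  zero non-responders) makes the logistic likelihood monotone; such terms
  are reported `non_estimable` rather than fitted, reproducing the
  situation where a response model cannot be fitted for a cluster with no
  responding patients. For Cox only zero-event levels are flagged, since
  censoring is not an outcome class.
* *Encodings*: cytogenetic risk enters as poor = 1 vs intermediate = 0
  with unevaluable patients excluded from models containing the term
  (configurable by pre-encoding the column).
* *2-year survival* is a crude proportion: survivors are patients with
  follow-up or death time >= 730 days, and the denominator includes
  patients censored earlier, matching the published denominators; the
  count of early-censored patients is returned as a flag because the
  convention can underestimate the true rate.

The multivariate guard requires at least 10 events by default. Ties are
handled by Efron's method (the likelier choice for this data scale;
software defaults differ and the choice is documented here).

## The synthetic cohort

`simulate_cohort()` generates the joint structure the analysis assumes,
with defaults matching the study conditions: 122 patients, a latent
resistant class drawn Bernoulli(0.20); composite response rates 0.29
(sensitive) and 0.00 (resistant) with a 60/40 CR vs CRp/CRi split;
RAS-mutation rates 0.44/0.10 with KRAS/NRAS mutually exclusive;
exponential survival with medians 154/237 days; LINE-1 maximum
demethylation means 15.4/26.3 percentage points; CpG-island methylation
elevated by +0.25 for the resistant class (CIMP-like) over a normal-blood
baseline (CGI sites ~Beta(1,9), non-CGI ~Beta(6,4)); clinical covariates
log-normal with class-specific medians from the published group tables.
Signature read counts are Binomial(depth, true methylation) at
Poisson-distributed depth.

Design choices worth making explicit:

* *Censoring* is administrative: uniform accrual over the first half of
  the study window with follow-up to the horizon, i.e. censoring times
  uniform on [horizon/2, horizon] (default horizon 1100 days, just beyond
  the longest printed follow-up). A censoring time uniform on the whole
  [0, horizon] would censor many patients early, which the published
  follow-up ranges (censored values all late) contradict.
* *Expression co-regulation*: the latent class is the single
  co-regulation factor — it shifts the gene means jointly (defaults, in
  Ct units: CDA, P15, CTCF, DNMT1 down 1.4; DNMT3A, DNMT3B up 1.4; P21
  unaffected) and residual variation is i.i.d. Normal with SD 0.5 plus
  0.15 technical SD per triplicate well. These values reproduce the
  qualitative cluster structure (a crisp ~20% resistant cluster, z4
  group separation of Cohen's d ≈ 2.5-3, ~85-90% agreement between the
  z4 < 0 rule and the cluster partition). The simulated z4 group means
  are somewhat more extreme than the published ones, which cannot be
  matched exactly by any two-Gaussian model whose component z-scores
  average to zero; qualitative fidelity was preferred.
* *Exponential survival* matches the printed medians but not the printed
  2-year rates: an exponential with median 237 days implies ~12%
  survival at 2 years before censoring losses, whereas the published
  sensitive-cluster rate is 21% — real AML survival has a longer tail
  than the exponential. Crude 2-year rates from the generator are
  therefore expected to undershoot, while medians, response rates and all
  directions of effect are calibrated.

What the generator does not emulate: within-class expression covariance
beyond the class factor (not reported in the source material), karyotype
structure beyond a three-level risk label, clonal VAF architecture,
batch/assay effects, and informative censoring. Tests passing on this
generator therefore validate the pipeline's statistical machinery and
directionality, not its behavior under real-world artifacts.

## Problem sizes and determinism

Everything stochastic takes a seed, and a fixed seed reproduces cohorts
and pipeline results byte-for-byte. The test-suite and acceptance runs use
deliberately compact problem sizes chosen as a balance of statistical
resolution and turnaround: 10-200 CpG sites for pipeline-level checks
(site count does not affect the expression/response/survival layers),
1000+ permutations for empirical p-values, 100-seed replication for
cluster-recovery and effect-direction properties, and cohorts of 500-5000
patients where parameter recovery or rate calibration is asserted. The
calibration bands used in tests are 3 binomial/Wald standard errors of the
relevant estimate.

## Known limitations

* The permutation test assumes exchangeability of samples under the null;
  strong batch structure would need stratified permutation, which is not
  implemented.
* PMM here uses one regressor; with many correlated sites a richer
  prediction model could impute better. The imputation fraction in the
  intended use (~2% missing after coverage filtering) makes this a minor
  concern.
* Wald confidence intervals are used for both Cox and logistic reports;
  profile-likelihood intervals would behave better near separation, but
  separated terms are excluded from fitting anyway.
* `compare_frequencies()` reconstructs reference counts by rounding
  frequency x n; supplying exact counts avoids rounding at very small
  frequencies.
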
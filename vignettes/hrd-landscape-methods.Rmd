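---
title: "Methods: HRD stratification, signature refitting, immune scoring and survival protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRD stratification, signature refitting, immune scoring and survival protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdscape)
```

# Scope and model

`hrdscape` stratifies a tumor cohort by homologous recombination
deficiency (HRD) and carries the stratification through group
comparison, enrichment and survival analysis. The pipeline has five
analytic layers, each exposed as ordinary functions:

1. **Genomic scars.** From allele-specific copy-number profiles it
   counts loss of heterozygosity (LOH), telomeric allelic imbalance
   (TAI) and large-scale state transitions (LST), and sums them into the
   HRD score. Samples with a sum strictly above 42 are HRD-high.
2. **Mutational signatures.** Per-sample 96-channel substitution
   catalogs are refit against a fixed signature dictionary by forward
   selection; the normalized weight of Signature 3 (the
   HR-deficiency-associated signature) above a strict 0.3 cutoff calls a
   sample S3-high.
3. **Expression scores.** Marker-panel means of log2-transformed
   expression provide cell-population abundances, five immune
   metagenes, a bounded TIL ratio score and a proliferation score.
4. **Classification and comparison.** BRCA1/2-mutated samples form one
   group regardless of score; wild-type samples split at the 42
   threshold into WT HRD-high and WT HRD-low. Groups are compared with
   Wilcoxon / Fisher / chi-square / Pearson tests and preranked GSEA.
5. **Survival.** Kaplan–Meier curves, log-rank tests, Cox models,
   maximally selected rank-statistic cutpoints, and a bootstrap
   stability-selection protocol around lasso-penalized Cox models.

A synthetic-cohort generator plants ground truth for every layer, so the
whole chain is testable against known answers.

# Scar scoring rules and parameters

All three rules operate on merged profiles (maximal runs of constant
allele-specific state) that tile each chromosome completely — telomere
contact is undefined on gapped profiles, so the readers enforce tiling.

* **LOH**: segments with `minor_cn = 0`, total copy number > 0, length
  strictly greater than `min_len` (default 15 Mb) and strictly shorter
  than the chromosome. Homozygous deletions (0+0) do not count: the
  standard reading of "LOH" requires a retained allele.
* **TAI**: allelic-imbalance segments (`major_cn != minor_cn`) of length
  at least 11 Mb that touch a chromosome end and do not overlap the
  centromere interval.
* **LST**: after smoothing away segments shorter than 3 Mb, breakpoints
  between adjacent segments of different state whose flanks are each at
  least 10 Mb. Smoothing absorbs the shortest sub-threshold segment
  first (leftmost on ties) into its longer neighbor (left neighbor on
  ties) and re-merges; this makes the result deterministic and
  insensitive to traversal order. Breakpoints inside the centromere
  interval are not counted by default; whether centromere-crossing
  transitions should count is genuinely ambiguous across published
  dialects of the rule, so it is a flag (`count_centromeric`), default
  off.

All four lengths are parameters with the defaults above, so alternative
dialects of the rules are reachable without code change. The packaged
genome tables (a 5-chromosome toy genome and an approximate hg19-scale
22-autosome table) supply chromosome lengths and centromere bounds and
are plain TSV, swappable by the user; the analysis does not depend on a
particular genome build beyond these coordinates.

# Signature refitting

Catalogs are normalized to 96-channel frequency profiles and fit by
greedy coordinate forward selection: starting from zero exposures, the
single-signature weight update with the largest closed-form reduction in
squared reconstruction error is applied until the relative improvement
falls below `tol` (default 1e-3) or `max_iter` (1000) updates. Weights
below `min_weight` (default 0.06, the conventional refitting default)
are zeroed and the survivors renormalized to sum to one. Tests verify
the fit against an independent projected-gradient least-squares solver
on the probability simplex: the forward-selection error is never
meaningfully above the simplex optimum, and three-signature mixtures at
5000–10000 mutations are recovered within ±0.03.

Two loud caveats. First, no trinucleotide-context (exome vs genome)
renormalization is applied — catalogs are assumed to be on the analysis
scale already. Second, the shipped five-signature dictionary is
synthetic: five well-separated unimodal channel profiles named after
signatures commonly refit in breast tumors. It makes mixtures
identifiable for testing; analyses of real catalogs should load a real
dictionary with `read_signature_dictionary()` (both the
rows-as-signatures and the COSMIC channels-in-rows layouts are
accepted).

# Expression scores

Every score is the arithmetic mean of `log2(x + 1)` expression over a
marker panel, applied uniformly to cell-population abundances,
metagenes, the four TIL components and proliferation. Averaging on the
log2 scale keeps all components of the TIL ratio
`(L + M) / (L + M + S + C)` nonnegative, so the ratio is bounded in
[0, 1]; a linear-scale average would not guarantee this. A score is
missing — never silently zero — when no panel gene is present, and the
TIL score is missing when any component is missing or the denominator
is zero.

The shipped panels (10 cell populations, five metagenes, four TIL
components, proliferation) are illustrative defaults assembled from
widely used lineage markers, stored as editable GMT files; any serious
application should replace them with curated lists. Scores are invariant
to genes outside the panels, so panel curation does not interact with
the rest of the matrix.

# Ranking and enrichment

Differential expression between two groups is summarized per gene by the
difference of group means of log2 expression, with a two-sided Wilcoxon
rank-sum p-value (exact enumeration over midrank assignments when both
groups have at most 8 samples, tie-corrected normal approximation with
continuity correction otherwise) and Bonferroni adjustment. The ranking
key is the mean difference with alphabetical tie-break, giving a total,
reproducible order. A negative-binomial count model is deliberately not
used here: the enrichment stage consumes only the monotone ranking, and
the rank statistic keeps the module self-contained; this is a
substitution, not a claim of equivalence.

The enrichment score is the classic weighted Kolmogorov–Smirnov running
sum (`weight_p = 1`): hits add `|stat|^p` normalized by the hit total,
misses subtract `1/(N - n_set)`, and ES is the signed maximum deviation.
ES lies in [-1, 1], is invariant to positive rescaling of the statistic
(both the hit increments and the maximum are scale-free after
normalization) and is negated by reversing the list. Significance uses
gene-label permutation — appropriate for preranked lists at desk scale —
with `NES = ES / mean(|null ES| of matching sign)` and
`p = (1 + k)/(1 + m)` over the same-sign null; if no null ES shares the
observed sign the guard value 1 is reported and flagged. BH q-values are
computed across the set collection.

# Survival stack

Kaplan–Meier, log-rank and Cox fits are delegated to the `survival`
package; the wrappers add input validation, Efron tie handling (the
modern default), explicit errors on non-convergence or separation, and a
median encoded as "not reached" rather than infinity. The test suite
cross-checks the Cox wrapper against an independently written
Newton–Raphson Efron partial-likelihood solver to 1e-4.

**Maximally selected rank statistics.** Candidate cutpoints are
midpoints between consecutive distinct covariate values inside a
quantile window (default 10%–90%). For each candidate the standardized
two-group log-rank statistic is computed from log-rank scores
(`event - Nelson–Aalen cumulative hazard`), and the cutoff is the
maximizer. The p-value of the maximal statistic is obtained by
permuting the covariate against the outcome, which accounts exactly for
the cutpoint search at desk scale; asymptotic bounds are deliberately
not implemented.

**Lasso-Cox and stability selection.** The bootstrap protocol follows
the published recipe: `n_bootstrap` resamples with replacement (default
500), a fresh cross-validated lambda per resample (child seeds derived
deterministically from the master seed), retention only for variables
selected in strictly more than 90% of resamples, and hazard-ratio
summaries as the mean and (5th, 95th) percentile interval of
`exp(coef)`. Candidates are expected to be pre-filtered to univariate
p < 0.10. Two genuinely open choices were resolved as follows:

* *Lambda rule.* The cross-validation rule defaults to `lambda.1se`
  (largest lambda within one standard error of the minimum-deviance
  lambda). Under the minimum-deviance rule the lasso is barely sparse on
  bootstrap resamples — in our simulations pure-noise covariates were
  selected in roughly 80–94% of resamples, which defeats a >90%
  retention rule. The one-standard-error rule restores the sparsity the
  protocol presupposes (noise selection frequencies near 0.1, planted
  signals at 1.0). `cv_rule = "min"` remains available.
* *HR summaries.* Hazard ratios for a retained variable are summarized
  over the bootstrap fits in which it was selected (mode
  `"selected_bootstraps"`, recorded in the result attributes), rather
  than by refitting a final model; the selected-bootstrap summaries are
  what the percentile interval is defined on.

CV folds are stratified on the event indicator (events spread
round-robin over folds) so every fold contains events; if a resample
cannot support that, it contributes an empty selection rather than an
error.

# The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` is the package's study bench. Its defaults are the
generator's fixed conditions: 60 samples, ~15% BRCA-mutated, roughly a
fifth of wild-type samples HRD-high; high-tier samples carry 15–25
planted events per scar component (HRD sums comfortably above 42) and
low-tier samples 0–3; HRD-high and mutated samples receive
Signature-3-dominated mixtures (S3 weight 0.5–0.8 vs 0–0.1) over
2000–6000 mutations; WT HRD-high samples carry a +2 log2 immune
abundance shift; survival is exponential proportional hazards
(baseline 0.02 events/month, censoring 0.01/month) with a planted
protective coefficient of -0.4 per log2 unit of lymphoid abundance.

Design choices worth knowing:

* **Non-interacting event placement.** Planted scar events are packed
  along chromosome arms as blocks separated by short balanced spacers,
  with the innermost block stretched to the centromere boundary, so no
  planted event leaks into another score; planted counts are therefore
  exact oracles. Interacting configurations are exercised separately by
  random-tiling profiles checked against brute-force counters.
* **BRCA–HRD coupling.** The published observation is an association,
  not a generative model. The generator draws scar tiers from the
  configured group proportions, then assigns the BRCA-mutated flag by
  weighted sampling without replacement with logistic weights in the
  planted HRD sum, and derives the intended group labels from the flag
  and the planted sum. This preserves the configured group sizes,
  produces the observed association, and keeps WT group recovery exact
  by construction.
* **Exponential survival and censoring** — the simplest model that
  satisfies proportional hazards; rates are configurable.

The generator does *not* emulate allele-frequency noise, subclonality,
tumor purity or ploidy, platform-specific expression normalization,
realistic marker covariance, or informative censoring. Passing tests
demonstrate the correctness of the algorithms under the stated
generative model, not robustness to these real-data complications.

# Numerical choices and degenerate inputs

* Strict boundaries throughout: HRD 42 is low, 43 is high; S3 0.30 is
  low, 0.31 is high; retention requires frequency strictly above 0.90.
* On-disk segment coordinates are 1-based inclusive (SEG convention);
  internal coordinates are 0-based half-open; readers and writers invert
  each other exactly.
* The 96 channels are fixed in the canonical lexicographic order
  (substitution class, then 5' and 3' flank); readers reorder arbitrary
  column orders into it, and fits are invariant to joint permutations.
* A catalog with a single mutation yields a valid one-hot-dominated
  exposure; an all-zero catalog is an error.
* Pairwise group p-values are reported raw, matching the common
  annotation convention for figure asterisks; the BH column in
  comparison tables and the "adjusted p" in reports use
  Benjamini–Hochberg and are labeled as this package's choice, since
  published tables often leave the adjustment method unstated.
* Permutation p-values use the add-one estimator `(1 + k)/(1 + m)`, so
  they are never zero.

# Validation scale

The shipped validation (the `test-acceptance.R` suite and
`scripts/acceptance.R`) runs at sizes chosen to give stable Monte-Carlo
estimates on a single CPU: 100 random profiles plus 50 generator
profiles for scar-oracle equivalence; 200 catalogs of 5000 mutations for
signature recovery; 1000 random sets for ES-oracle identity and 500
replicates for null calibration; 2000 samples for the KM closed form;
500 and 200 replicates for log-rank and maxstat size; 20 replicates of
the stability protocol at 200 bootstraps (the protocol default remains
500; 200 is the documented reduced setting for validation runs), with
5-fold CV and a 30-point lambda path as the numerical knobs. The
acceptance script reports the same quantities at moderately reduced
replicate counts.

# Known limitations

* The scar rules implement one published dialect per component; scores
  from other pipelines can differ systematically (e.g. in length
  thresholds or centromere handling), which is why all lengths are
  parameters.
* The shipped marker panels and signature dictionary are illustrative;
  conclusions about real cohorts require curated replacements.
* Gene-label permutation GSEA ignores inter-gene correlation; phenotype
  permutation is out of scope.
* The stability-selection hazard-ratio intervals are percentile
  summaries over bootstrap fits, not confidence intervals with
  guaranteed coverage.
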
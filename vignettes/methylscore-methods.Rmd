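---
title: "Methods: 5mC-regulator subtyping and the DNA methylation score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 5mC-regulator subtyping and the DNA methylation score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscore)
```

This vignette is the package's own account of the statistical machinery:
what each stage assumes, which knobs matter, how the synthetic cohorts are
built, and where the genuinely open design choices were settled.

## The analysis chain

The pipeline formalizes a common epigenomic subtyping design. Tumors are
first grouped by the expression of the DNA 5-methylcytosine (5mC)
machinery — a ~20-gene panel of writers (DNMTs), erasers (TETs) and
readers (MBD/ZBTB/UHRF proteins and the uracil-family glycosylases).
Genes that differ between those groups are then distilled into a single
per-sample prognostic index, the DNA methylation score (DMS), which is
dichotomized at a data-driven cutpoint and evaluated against overall
survival. Each stage consumes the previous stage's table, so the chain is
`preprocess -> cluster -> deg -> score -> survival`, with descriptive
landscape statistics and enrichment analyses alongside.

## Cohort cleaning

Four sample-level predicates remove: samples without any follow-up,
samples with unknown survival time, samples with survival below
`min_days` (default 30 days; a sample at exactly 30 is kept — the rule is
*strictly less than*), and samples with unknown status. Because the rules
are predicates, the retained set is independent of the order they are
applied in, and each rule's count is reported. Expression rows whose
identifier maps to several genes (separators `///` or `;`, configurable)
are removed; remaining duplicate symbols collapse to per-sample medians.

Gene z-scores use the population SD (divisor *n*). Nothing downstream
depends on the choice, but fixing it makes results bit-reproducible;
`ddof = 1` is available.

## Consensus clustering

`consensus_cluster()` follows the Monti resampling scheme: draw
`ceiling(p_item * n)` samples without replacement (default `p_item = 0.8`),
partition each subsample with PAM (k-medoids) on 1 − Pearson correlation
over the z-scored feature genes, and record for every sample pair the
fraction of co-drawn resamples in which the pair was co-clustered. The
final subtypes at each k cut an average-linkage tree of 1 − consensus —
the consensus matrix, not any single PAM run, defines the assignment.
The default of 1000 resamples is the production setting; 100 resamples
already stabilize the assignment on cohorts of ~150 samples (the test
suite uses 40–100 for speed, and the planted-recovery checks pass with
adjusted Rand index ≥ 0.95 at 100 resamples).

The PAM implementation is the classic build + swap search, deterministic
by construction: greedy initialization, then the *first* strictly
improving (medoid, non-medoid) exchange in fixed index order, repeated
until no exchange improves. PAM is a local search: on roughly one in ten
random tiny instances it terminates in a swap-local optimum a few percent
above the global minimum (the reference `cluster::pam` behaves the same
way); the tests verify swap-optimality by exhaustive single-exchange
enumeration and global optimality on the majority of instances.

**Choosing k.** The package reports the consensus-CDF area, its delta-area
increments, and the proportion of ambiguous clustering
(PAC = CDF(0.9) − CDF(0.1)). The recommendation in `select_k()` is the PAC
minimum (ties toward smaller k). A delta-area threshold rule was
implemented first and rejected: the raw CDF area grows mechanically with
k, so any fixed threshold over-splits even perfectly separated cohorts,
while PAC is near 0 exactly at the planted k and large everywhere on
structureless data. When even the best PAC exceeds `pac_confident`
(default 0.2) the recommendation is flagged low-confidence. The
recommendation never overrides a user-supplied k.

## Differential expression

`moderated_t()` fits the two-group linear model per gene and shrinks the
residual variances toward a common prior estimated by moment matching on
`log s²` (digamma/trigamma scheme; the trigamma equation is solved by
Newton iteration). The posterior variance is the df-weighted blend of the
prior and per-gene variances; the moderated t is referred to a
t-distribution on prior + residual df, capped at the pooled residual df.
With `d0_override = 0` the statistic reduces exactly to the ordinary
pooled-variance t-test — the test suite checks both that reduction and
numerical agreement with an independent empirical-Bayes implementation to
1e-10.

DEGs are called at raw p < 0.05 *and* |log2FC| > 1 (both strict); the
BH-adjusted p is always reported and `use_adjusted = TRUE` switches the
filter. Raw p is the default because it is the conventional volcano rule
this analysis style uses; adjusted-p filtering is better practice for
discovery and is one flag away. With three subtypes the default contrast
is cluster 2 vs cluster 3 (clusters are numbered by decreasing size);
any pair can be requested.

## The DNA methylation score

Candidate genes (the DEGs) are screened by univariate Cox regression
(Breslow tie handling, Wald p < 0.05, either hazard direction). Screened
genes are z-scored and decomposed by SVD; each sample's DMS is the sum of
its first two principal-component scores. The per-gene summation that a
naive reading of "sum of PC1 over genes" would suggest is already
absorbed in the projection — a PC score *is* a weighted sum over genes —
so the score is `s₁·PC1 + s₂·PC2` per sample, the construction this
signature-score family (TMEscore-style) uses.

PCA is sign-ambiguous, and without a convention "high DMS" would be
arbitrary. The orientation rule: each component's sign is chosen so that
the oriented score correlates non-negatively with the mean z-expression of
the protective screened genes (HR < 1). High DMS therefore means
protective expression and better expected prognosis. If no screened gene
has HR < 1 the rule anchors on the negated risk-gene mean instead.

**Scoring external cohorts.** `apply_dms()` standardizes the new cohort
with its *own* per-gene means/SDs before projecting onto the stored
loadings — cross-platform location/scale shifts would otherwise dominate
the score. `train_scale = TRUE` reuses the training constants for
same-platform splits. Missing model genes are imputed at z = 0 (counted
and reported); at least 80% of model genes must be present. Both re-fit
and projection semantics are thus available; projection is the default
because it keeps the validation honest (no re-estimation on the test
cohort).

Degenerate inputs: a single screened gene falls back to that gene's
z-score (PC2 = 0, warning); a rank-1 standardized matrix sets PC2 to 0.

## Survival stratification

Kaplan–Meier curves carry Greenwood variances; the median survival is the
smallest observed time with S(t) ≤ 0.5 (undefined when the curve never
reaches 0.5). The log-rank test is the standard observed-minus-expected
statistic with hypergeometric variance, for any number of groups.

`find_cutpoint()` implements maximal selection: candidate cutpoints are
the *midpoints between consecutive unique score values* (so the result
does not depend on score granularity) whose induced split leaves at least
`minprop` (default 0.1) of samples on each side; the selected cutpoint
maximizes the absolute standardized two-group log-rank statistic, ties
toward the smaller value. The naive p-value at the selected cutpoint is
reported but explicitly flagged `selection_biased` — maximizing over
candidates inflates the statistic, which the test suite demonstrates by
simulation — and an optional permutation-adjusted p re-selects the
maximum over permuted scores.

## Enrichment

GSEA uses the weighted Kolmogorov–Smirnov running sum (hits advance by
|stat|^p normalized within the set, default p = 1; misses retreat by
1/(N−K)); the null is gene-set permutation — random same-size sets drawn
from the ranked list — because the small cohorts this pipeline targets
make phenotype permutation unstable. p-values are empirical within the
same-sign null (so with 1000 permutations the smallest attainable p is
about 2/1000), NES divides ES by the mean |null ES| of the same sign, and
BH adjustment is applied across sets. Over-representation is the exact
hypergeometric upper tail. Per-sample signature scores offer `mean_z`
(mean z-score of member genes — transparent, linear) and an ssGSEA-style
rank integral (exponent 0.25). Immune-cell and immune-factor panels are
supplied by the user as GMT files; the package deliberately ships no
curated gene-set database, and deconvolution methods are out of scope —
signature scoring is the stand-in.

## The synthetic cohort generator

`simulate_cohort()` emulates exactly the structure the chain assumes:

* **Regulator panel** (default 20 genes, real panel symbols): per-gene
  cluster means drawn N(0, (cluster_shift·noise_sd)²) over `k_true`
  clusters (default 3), plus N(0, noise_sd²) noise. `cluster_shift = 0`
  plants no structure.
* **Background genes** (default 1000, of which 100 true DEGs shifted by
  `deg_log2fc` in one cluster each, cycling over clusters; the rest
  i.i.d. noise).
* **Latent prognostic score**: the standardized first principal direction
  of the realized true-DEG block — tying survival to the DEG block (not
  the panel) makes the full chain "clusters → DEGs → score → survival"
  recoverable by construction.
* **Survival**: exponential event times with hazard
  `baseline_hazard · exp(−surv_beta · score)` (positive `surv_beta` makes
  a high score protective); a Weibull variant with the same
  proportional-hazards form is available. Censoring is independent with
  the same form, its rate solved numerically so the expected censored
  fraction equals `censor_rate`.
* **Mutations / CNV**: per-regulator Bernoulli calls at planted
  frequencies (defaults 0.19/0.15/0.12 for the first three regulators,
  tapering to 0.02 — the familiar pattern where a few regulators dominate
  the mutation landscape) and 5-level CNV calls at planted gain/loss
  frequencies.

Defaults mirror a mid-size glioma cohort: 143 samples, survival on the
scale of hundreds of days (`baseline_hazard = log(2)/500` per day), 30%
censoring. What the generator does *not* emulate: count-level RNA-seq
noise (everything is Gaussian on the log2 scale), batch effects,
copy-number-to-expression coupling, and non-proportional hazards. Tests
passing on these cohorts therefore demonstrate correctness of the
algorithms and the recoverability of planted structure — not robustness
to every pathology of real data.

The end-to-end checks use `k_true = 2` so that the DEG contrast *is* the
two discovered subtypes; the three-subtype default instead exercises the
pairwise 2-vs-3 contrast. Problem sizes in the test suite (cohorts of
40–200 samples, 300–5000 genes, 40–100 consensus resamples, 20-seed
replicate loops) were chosen as the smallest sizes at which the planted
effects are comfortably identifiable.

## Numerical conventions

* Every stochastic function takes an explicit integer seed and restores
  the caller's RNG state; identical seed + configuration is byte-identical
  through the TSV writers (fixed significant-digit formatting).
* PAM ties (equidistant points, equal-gain swaps) resolve by first index;
  cluster labels are cosmetic and always compared by adjusted Rand index.
* Wilcoxon tests are exact when the smaller group has ≤ 10 samples and
  there are no ties, otherwise normal approximation with tie and
  continuity correction.
* Zero-variance genes: dropped with a warning in z-scoring, flagged
  (p = 1) in differential expression, flagged `constant` and excluded in
  Cox screening.
* Correlation p-values use the t approximation
  `t = r·sqrt((n−2)/(1−r²))`, for Spearman as well (adequate at the
  cohort sizes targeted; exact small-n Spearman tails are not needed
  anywhere in the chain).

## Known limitations

* The DMS inherits PCA's linearity; strongly non-linear prognostic
  structure would load across many components and be diluted.
* The maximally selected cutpoint's naive p is anti-conservative by
  design of the selection; use the permutation p for inference.
* Univariate Cox screening ignores correlation among genes; it is a
  screen, not a multivariate model (penalized models are out of scope).
* Consensus clustering with PAM inherits PAM's local-search character;
  consensus aggregation averages this out across resamples, but single
  `pam_cluster()` calls on adversarial dissimilarities can be suboptimal.
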
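---
title: "Compositional balance models for gut-microbiome discrimination of Alzheimer's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional balance models for gut-microbiome discrimination of Alzheimer's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adbalance)
```

## The problem

Shotgun-metagenomic profiling of stool yields per-sample abundance tables —
genera on the taxonomic side, Gene Ontology (GO) terms and KEGG orthologs
(KO) on the functional side — and the question is how well such tables,
alone and combined with routine clinical covariates, discriminate
amyloid-positive Alzheimer's disease (AD) patients from cognitively healthy
controls (HC). `adbalance` implements that discrimination pipeline end to
end: compositional preprocessing, per-block feature selection and model
shrinkage, ensemble stacking, ROC evaluation, and the accompanying cohort
statistics. Because the cohort's raw sequencing data cannot ship with a
package, a synthetic cohort generator reproduces the statistical structure
the analysis assumes, so every stage is testable at desk scale.

## Data model and preprocessing

An abundance table is samples × features, either raw classifier hit counts
or hits per million reads (HPM): hits divided by the sample's read count,
times 10^6. HPM removes sequencing-depth differences but leaves the data
compositional — only relative information is meaningful — so all modelling
runs through log-ratio methods:

* **clr**: log abundance centred by the sample's mean log abundance.
* **ilr**: an orthonormal basis of log contrasts; we use the pivot
  (sequential binary) partition over features ordered by id. Any ilr basis
  is an isometry of the clr geometry, so the principal-component analysis
  downstream is basis-insensitive in the variance it captures; the pivot
  basis is simply a deterministic choice.
* **balance**: `sqrt(rs/(r+s)) * ln(g(numerator)/g(denominator))` for two
  disjoint feature groups of sizes r and s, `g` the geometric mean.

Log ratios need strictly positive parts. The default zero replacement is
multiplicative: zeros are imputed as 0.65 × the smallest non-zero value of
the table and non-zero values are untouched; a `pseudocount` variant adds
the constant everywhere. Features that are zero in every sample are dropped
with a warning — they carry no log-ratio information. The replacement value
is computed on the full table before the train/validation split; it is a
single scale constant shared by both parts, and scale constants cancel in
every log-ratio statistic, so this does not leak label information.

Natural logs are used inside clr/ilr/balances (the balance coefficient
convention requires them); base-10 logs are used only for the effect
summaries below, where "difference of logarithmised medians" is reported on
the log10 HPM scale.

## Block models

For each feature block the training set is processed as follows.

1. **Pre-selection.** Each feature is tested for an AD-vs-HC shift with the
   two-sided Wilcoxon rank-sum test (exact enumeration when the combined n
   is ≤ 20 without ties, otherwise the tie-corrected normal approximation).
   Features with p below `alpha` (default 0.05, unadjusted — configurable)
   survive, ordered by p; at most `max_features` (default 25) enter the
   next stage.

2. **Representation.** The default design is a single two-group balance:
   features whose training difference of log10 medians is positive (higher
   in AD) form the numerator, the rest the denominator. If every selected
   feature sits on one side, the other side falls back to the complement of
   the selected set within the table, so the contrast remains a proper
   balance. A `log_features` alternative (logistic regression on log10 HPM
   columns) is available.

3. **Shrinkage.** Backward elimination under stratified 5-fold × 30-repeat
   cross-validation: at each step the feature whose removal maximises the
   mean CV AUROC is dropped (ties broken towards the larger pre-selection
   p-value, then lexicographically), recording the trajectory down to one
   feature. The chosen model is, by default, the smallest feature set whose
   mean CV AUROC is within one standard deviation of the trajectory maximum
   (a parsimony rule; plain maximum is selectable). All fold assignments
   derive from the CV seed, so trajectories are bit-reproducible.

4. **Final fit.** Ridge-penalised logistic regression (Newton/IRLS, penalty
   `ridge/2 * sum(beta^2)` on non-intercept terms, default ridge 1e-4 —
   negligible bias, but it keeps near-separated fits finite) of diagnosis on
   the chosen design over the whole training set.

The clinical block is a fixed logistic model on age, gender, BMI and ApoE
ε4 allele count, with no shrinkage; samples missing ApoE are dropped with a
message.

## Ensemble

Components are stacked: each component is refitted per cross-validation
fold (the same 5 × 30 scheme, shared fold assignments) and its held-out
probabilities are recorded; with repeats, each sample's out-of-fold entry
is the mean over repeats. A logistic model of diagnosis on those
out-of-fold probabilities is the combiner, so it never learns from
resubstitution-optimistic inputs. Components are kept as fitted on the full
training set for validation prediction, the standard stacking protocol. A
`mean_probability` combiner (no fitting) is available as the simplest
alternative; both are first-class because the original analysis names only
"ensemble learning".

## Evaluation

The cohort is split once into training and validation parts, stratified by
diagnosis with per-class training counts of round-half-up(class n ×
fraction) at the default 3:1 ratio; an explicit `counts` override exists
because published analyses sometimes realize slightly different counts than
strict rounding (the reference cohort's realized 59/73 training split is
reproduced that way). AUROC is the Mann-Whitney estimator (ties worth one
half), identical to the trapezoidal area under the empirical ROC curve.
Confidence intervals default to DeLong, with a stratified bootstrap (2,000
replicates) as the alternative and as the automatic fallback when the
DeLong variance degenerates. Cutpoints maximise the Youden index, ties to
the lower threshold. Training-set AUROCs are resubstitution estimates and
are labelled as such alongside the CV estimates; both are reported because
which one a given published figure shows is usually ambiguous.

## Cohort statistics

`compare_groups()` mirrors conventional baseline-table practice: t-tests
for age and BMI (pooled or Welch variance according to a mean-centred
Levene test at α = 0.05), Mann-Whitney U for the bounded scales (MMSE,
GDS), and Pearson chi-square without continuity correction for gender,
ApoE and medication flags. The no-correction choice is deliberate: it
reproduces the published contingency-table p-values exactly (gender
p = 0.2565, ApoE p = 0.0036 from the printed tables).

The covariate-influence test asks whether a binary flag (say antidepressant
use) is associated with overall genus composition: HPM → zero replacement →
ilr → PCA on centred, unscaled coordinates keeping the smallest component
set reaching 95% of the variance → two-sample Hotelling T² on the scores.
ilr coordinates are already scale-free, which is why the PCA is unscaled.
The T² statistic uses the pooled covariance and the exact F reference
distribution; it requires n₁ + n₂ − 2 > k, and the variance threshold is
the right knob when k is too large.

## Effect reporting

Per-feature effects are differences of logarithmised medians,
`log10(median AD) − log10(median HC)`: negative means higher in healthy
controls. The log base is a reporting convention only (configurable);
shipped fixtures store the published values verbatim, so fixture-driven
results do not depend on it. Group medians of even-sized groups are the
mean of the two central order statistics. Phylum attribution counts
features per phylum overall and within each effect sign, with percentages
relative to the sign group. Feature–clinical associations default to
Spearman rank correlation (robust for abundances; Pearson selectable —
which one the reference tables used is not stated), computed
pairwise-complete, with CSF markers correlated over AD samples only since
controls have no CSF in this design.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
real microbiomes:

* **Clinical covariates** follow the published cohort margins: group-wise
  normal age/BMI/MMSE/GDS (ages truncated to [50, 95], HC MMSE truncated at
  ≥ 27 per the inclusion rule), Bernoulli gender and medication flags at
  the printed rates, categorical ApoE ε4 counts at the printed genotype
  frequencies, and CSF markers for AD only. Truncated normals are
  mean-calibrated: the location is shifted (closed-form truncated mean,
  solved by `uniroot`) so that the realized mean equals the printed target
  despite asymmetric truncation — plain truncation would, e.g., bias the AD
  age mean upward by ~0.3 years.
* **Abundances** follow a log-normal latent model closed to the simplex:
  feature f has baseline log10 relative abundance a_f (drawn once per
  block; planted features sit at the baseline mean so they stay above the
  zero floor), each sample adds Normal(0, `sample_logsd`) noise, AD samples
  add the planted δ_f, and counts are multinomial at the configured depth.
  The log-normal choice makes "difference of log10 medians" the natural
  planted parameter: the observed HPM effect recovers δ_f up to closure,
  which is negligible while planted features are a small share of the
  composition. A Dirichlet-multinomial would not offer such a direct
  parameterisation.
* **Defaults as study conditions.** 100 HC / 75 AD; three blocks (genera,
  GO, KO) of 300 features each, embedding the published 18/17/26 effect
  sizes among noise; desk-scale depth of 10^5 reads (the study's 40–50
  million is a configuration switch away — HPM expectations are
  depth-invariant, so desk depth changes only count quantisation);
  `sample_logsd` = 0.2 on the log10 scale, chosen once so that effects of
  the printed magnitudes (|δ| from 0.005 to 0.28) are recoverable and
  discriminable at the study's sample sizes, consistent with the
  discrimination the study reports. Clinical covariates are generated
  independently of abundances given diagnosis, because the blocks are
  modelled separately and no joint structure is asserted anywhere.

What passing tests on this generator do **not** show: robustness to real
microbiome features such as overdispersion beyond log-normal,
taxon–taxon correlation, compositional zeros that are structural rather
than sampling, batch effects, or profiler-specific biases. The generator
validates the pipeline's statistical machinery, not its field performance.

## Numerical choices and degenerate inputs

* Logistic IRLS: step damping (tiny Hessian ridge, step halving) for
  stability; the optimum is unchanged. Perfect separation at ridge 0 is
  detected and reported as an error instructing a positive ridge.
* Wilcoxon with zero rank variance (a feature identical in every sample)
  reports p = 1 rather than NaN.
* Elimination and extreme-feature ties break deterministically
  (pre-selection p, then lexicographic feature id).
* All randomness flows from explicit seeds; every generator and CV routine
  restores the global RNG state.
* Problem sizes used by the shipped tests: the end-to-end run uses the
  default study-like bundle (175 samples, 300 features per block, 5 × 30
  CV, elimination capped at 25 pre-selected features); calibration checks
  use 10,000 null features for the Wilcoxon error rate, 2,000 replicates
  for the Hotelling null, and 20 seeds for the null-pipeline and
  effect-recovery properties.

## Known limitations

* The exact train/validation partition, CV seeds, pre-selection threshold
  and combiner of the reference analysis are not recoverable from its
  description; the corresponding knobs here are explicit, seeded and
  documented, but numeric agreement with the published AUROCs is neither
  expected nor claimed — those depend on the real cohort.
* The balance construction searches only the two-group split given by
  effect signs, not the full space of sequential binary partitions.
* No multiplicity correction is applied across baseline-table tests or
  pre-selection p-values, matching the reference procedure.
* Correlation tables are descriptive; no significance procedure is
  attached to them.
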
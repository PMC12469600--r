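---
title: "Methods: model-free allelic polygenic risk scores, stratified by sex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-free allelic polygenic risk scores, stratified by sex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prspredict)
```

## The model and its assumptions

`prspredict` predicts a binary phenotype (case/control) from biallelic
genotype dosages without fitting a regression model. The per-individual
score is a weighted average of minor-allele dosages,

$$\mathrm{PRS}_j = \frac{1}{2N}\sum_{i=1}^{N} \log(\mathrm{OR}_i)\,g_{ij},$$

with three deliberate modelling choices:

* **Weights are marginal allelic odds ratios.** Each variant's weight is
  the log of the cross-product ratio of minor/major allele counts in
  cases versus controls. This treats alleles (not genotypes) as the
  sampling unit, which is exact under Hardy–Weinberg proportions and
  multiplicative allelic effects, and is robust — but *marginal*: no
  covariate or inter-variant adjustment is done. Variants are assumed
  approximately independent, which is why LD pruning precedes scoring.
* **Selection is by predictive ability, not significance.** The top-$N$
  variants by raw odds ratio enter the score. A configuration switch
  (`ranking_key = "abs_log_or"`) ranks by $|\log \mathrm{OR}|$ instead,
  which also admits protective variants; the default follows the raw-OR
  convention because with it "top" reads directly as "largest risk".
* **Classification is a percentile rule.** An individual is called a
  case when their score *strictly exceeds* the 95th percentile of the
  control-score distribution. This is analogous to clinical reference
  ranges (e.g. lipid levels above the 95th population percentile) and
  fixes the false-positive rate near 5% by construction, at any $N$.

Males and females are analysed as two fully independent datasets (same
variants, disjoint samples). Nothing is pooled: counts, odds ratios,
rankings, thresholds and cross-validated accuracies are all per-sex.
Agreement between the sexes is then a genuine replication, quantified by
the overlap test below.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `max_missing_rate` | 0.10 | variant removed when missing-call fraction strictly exceeds this |
| `min_maf` | 0.01 | minor allele frequency floor (strict `<` removes) |
| `hwe_alpha` | 1e-3 | exact-test threshold, controls only; common QC practice |
| `window`, `step`, `vif_threshold` | 50, 5, 2.0 | VIF pruning window (variants), increment, and 1/(1−R²) cap |
| `percentile` | 95 | control-score percentile for the case threshold |
| grid of $N$ | 5 … 50,000 | variant counts swept for accuracy-vs-N curves |
| `n_reps` | 100,000 | Monte-Carlo replicates for the overlap null |

The natural log is used in the score; the base only rescales every score
by the same constant and therefore cannot change any percentile-based
classification. Missing genotypes are skipped in the numerator and, by
default, the denominator uses $2N_j$ with $N_j$ the number of
*non-missing* selected variants for individual $j$ (a fixed-$2N$ mode
exists for exact comparability with the textbook formula).

## Quality control conventions

Filters run in a fixed order — call rate, monomorphy, Hardy–Weinberg in
controls, MAF, LD pruning — and a variant failing several is attributed
to the first. The Hardy–Weinberg test is the exact conditional test
(sum of probabilities of all heterozygote counts no more likely than the
observed one), applied to controls only, since true associations can
distort genotype proportions in cases. Pruning slides a window of
`window` variants per chromosome, mean-imputes missing dosages within
the window, and repeatedly removes the variant with the largest
variance-inflation factor until all VIFs are at or below the threshold;
whole sweeps repeat until stable, which makes the operation idempotent.
Bit-exact parity with PLINK's `--indep` is explicitly *not* promised —
only the algorithmic contract above.

## Leave-one-out cross-validation

Every reported accuracy is validated by the leave-one-out scheme: for
each of the $K$ individuals, allele counts, odds ratios, the ranking,
the top-$N$ selection, the weights and the control-score threshold are
all recomputed without that individual (the threshold additionally
excludes the individual when they are a control), and only then is the
individual scored and classified. The procedure involves no randomness.
Internally the per-fold counts are obtained by an incremental
decrement/increment of integer allele counts, which the test suite
proves exactly equal to literally deleting the row and refitting. QC is
*not* re-run per fold: filtering happens once, before cross-validation,
matching how the pipeline is used in practice.

Because the held-out individual never informs their own rule, the
leave-one-out accuracy under a null cohort sits at the analytic level
$(0.05\,n_\text{case} + 0.95\,n_\text{control})/n$ — no optimistic bias.
The test suite asserts this.

## The overlap replication test

Let $m$ be the variant universe (after QC), and let the two sexes
contribute top lists of sizes $k_1$ and $k_2$ with $N_s$ variants in
common. The null hypothesis is that each list is a uniform-random subset
of the universe. The default test literally redraws both subsets
`n_reps` times and counts overlaps; the empirical significance is the
add-one estimator $(\#\{\text{overlap} \ge N_s\} + 1)/(n_\text{reps}+1)$,
which can never be zero. The exact null distribution of the overlap is
hypergeometric with population $m$, $k_1$ successes and $k_2$ draws
(mean $k_1 k_2 / m$), and the package exposes it both as a fast sampling
path and as the analytic cross-check; the test suite verifies the two
agree, and validates the hypergeometric itself against exhaustive subset
enumeration at small $m$.

## ROC smoothing and AUC

Sweeping $N$ at a fixed percentile threshold produces a *ragged*
(FPR, TPR) sequence: it is not a conventional threshold-swept ROC curve,
and TPR need not rise monotonically with FPR. Both coordinate sequences
are therefore repeatedly replaced by overlapping 3-point moving averages
(endpoints fixed) until the curve satisfies the two conditions of a
proper ROC curve — TPR ≥ FPR everywhere, and TPR non-decreasing along
increasing FPR — after which the AUC is computed by trapezoid with the
corners (0,0) and (1,1) appended, averaging TPR over duplicated FPR
values. One published statement of the first condition reads
"FPR ≥ TPR"; the package implements TPR ≥ FPR, since a curve below the
diagonal contradicts AUC ≥ 0.5, which the same source asserts. Repeated
3-point averaging with fixed endpoints converges to the linear
interpolation between the endpoints, so the iteration terminates
whenever the endpoints themselves conform; non-conforming endpoints
produce a convergence error rather than a non-conforming curve.

Accuracy, not AUC, is the package's headline metric: ACC =
$(a+d)/\text{total}$ is the proportion of correct predictions and treats
cases and controls symmetrically. (One published formula prints ACC as
$(a+c)/\text{total}$; that contradicts both the verbal definition and
the worked misclassification rates, e.g. $26/932 = 2.8\%$ with
$a=384, b=0, c=26, d=522$, so the package implements the verbal
definition.)

## The synthetic cohort generator

`simulate_cohort()` emulates exactly the statistical structure the
pipeline assumes: biallelic variants in linkage equilibrium, genotypes
in Hardy–Weinberg proportions with MAF uniform over a configurable
range, and a logistic liability that is log-additive in the planted
per-allele effects, with sex-specific causal sets (shared causal
variants carry the same effect in both sexes). The logistic intercept is
solved by bisection so the expected case fraction matches the target;
missingness is uniform. Defaults mirror the motivating study's cohort
shape — 2164 males, 932 females, case fraction 0.337 — at a desk-scale
2000 variants, with 50 + 50 + 20 sex-specific/shared causal variants of
log OR in (0.2, 0.7) and 0.2% missing calls, typical of array data.

What the generator does **not** emulate: realistic LD structure (pruning
fixtures plant correlation explicitly), population stratification and
admixture, genotyping batch effects, dominance or epistasis, and
X-chromosome hemizygosity (all variants are treated as autosomal
diploid). A green test therefore establishes correctness of the
*algorithms* under the model's own assumptions — not robustness to the
confounders of real cohorts.

Two quantitative caveats discovered while validating the generator, both
consequences of odds-ratio non-collapsibility:

* **Attenuation of marginal odds ratios.** The planted $\beta$ is the
  *conditional* per-allele log odds ratio. The *marginal* allelic OR the
  scoring module estimates is attenuated by the liability variance of
  the remaining causal variants (roughly by
  $\sqrt{\pi^2/3 \,/\, (\pi^2/3 + V)}$). Parameter-recovery tests
  therefore plant effects in the small-effect regime
  ($\beta \in (0.05, 0.15)$ over 50 causal variants at $n = 4000$),
  where the attenuation is under 3% and recovery within 3 standard
  errors is a well-posed criterion — and which is also the regime the
  polygenic-trait literature describes.
* **Accuracy ceiling at high case fractions.** With a third of the
  cohort affected, the 95th-percentile rule bounds accuracy near
  $\mathrm{TPR}\cdot 0.337 + 0.95\cdot 0.663$; even the oracle
  classifier built from the true planted effects of 30 strong variants
  (per-allele OR ≈ 4, $n = 400$) reaches only ACC ≈ 0.82, because the
  many low-liability "lucky" cases of a logistic model are inherently
  unpredictable. The strong-effect cross-validation test asserts a wide
  margin over the analytic null level rather than a fixed 0.9.

## Numerical conventions and degenerate inputs

* Percentiles use linear interpolation between order statistics
  (R quantile type 7); a nearest-rank mode exists. The convention
  matters at small control counts and is therefore explicit.
* Threshold ties go to "control" (the rule is *strictly exceeds*).
* Zero cells in a 2×2 allele table trigger the Haldane–Anscombe +0.5 on
  all four cells, keeping every odds ratio finite and positive.
* Ranking ties preserve the original variant order; VIF ties remove the
  larger variant index — both make reruns bit-identical.
* Decision-table metrics with zero denominators are `NA` (flagged, never
  `NaN`); an infinite odds ratio ($bc = 0 < ad$) carries an explicit
  flag.
* All-missing variants count as monomorphic in QC; an individual whose
  selected genotypes are all missing gets a missing score and a missing
  prediction, tallied separately.
* Permutation and Monte-Carlo p-values use add-one estimators and
  required, recorded seeds.
* The exact Hardy–Weinberg p-value compares probabilities with a
  $1+10^{-9}$ relative tolerance so floating-point noise cannot break
  ties in the "at most as probable" sum.

## Known limitations

Beyond the generator caveats above: odds ratios are unadjusted (no
covariates, no principal components); summary-statistic input is out of
scope by design (the method's point is individual genotypes); the
percentile rule fixes specificity rather than optimizing a loss; and the
overlap test conditions only on list sizes, not on any structure (e.g.
LD clumps) within the lists.
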
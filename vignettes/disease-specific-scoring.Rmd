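---
title: "Disease-specific aggregation of tissue-level variant scores: models and methods"
author: "dscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-specific aggregation of tissue-level variant scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscore)
```

## The problem

Most non-coding variant prioritization scores are either organism-wide
(one number per variant) or tissue-specific (one number per variant per
tissue or cell type). When the question is "which of these variants matter
for *this* disease", neither is quite right: organism-wide scores reward
functional impact in tissues irrelevant to the disease, and tissue-level
scores leave the user to guess which tissues to look at.

`dscore` aggregates tissue-level chromatin-accessibility scores into a
*disease-specific* score by learning, for each disease, a weight per
tissue from GWAS-derived disease-associated variants and matched control
variants. The learned weights are interpretable — they nominate the
tissues through which the disease's non-coding variants appear to act —
and they support a downstream disease–disease similarity analysis.

## The model

Each variant $i$ carries a score vector $x_i \in \mathbb{R}^d_{\ge 0}$
over $d$ tissue contexts, with tissue-mean $\bar{x}_i = \frac1d \sum_k
x_{ik}$. Labels $y_i$ mark disease-associated variants (1) versus matched
controls (0). The model is a logistic regression

$$\log \frac{p_i}{1 - p_i} = \alpha_0 + \alpha\, \bar{x}_i + \beta' x_i,
\qquad \alpha \ge 0,$$

fitted by minimizing the class-weighted mean negative log-likelihood plus
a ridge penalty $\frac{\lambda}{2} \lVert \beta \rVert_2^2$. Three
structural choices matter:

* **The tissue-mean column is unpenalized and sign-constrained.** As
  $\lambda \to \infty$ the tissue weights vanish and the model degrades
  gracefully to (a non-negatively scaled) tissue-mean baseline — the
  disease-agnostic score — rather than to a constant or an inverted
  baseline. A test asserts that at very large $\lambda$ the model's
  ranking is Spearman-identical to the tissue-mean ranking.
* **Class weights** $w_i = n / (2 n_{\text{class}(i)})$ give the positive
  and control classes equal total weight, so the heavy 1:10 imbalance of
  the benchmark design does not dominate the likelihood.
* **Features are standardized internally** (centered, scaled by the
  population standard deviation) before penalization, and coefficients
  are reported back on the original score scale. A flag
  (`standardize = FALSE`) disables this.

The solver is a damped Newton iteration with an exact active-set step for
the single bound: the unconstrained optimum is accepted if its baseline
coefficient is non-negative; otherwise the model is refit with the
baseline term pinned at zero, which for a convex problem with one bound
is the boundary optimum. Convergence requires a gradient max-norm of
$10^{-6}$ on the standardized scale; non-convergence is an error, never a
silent result.

## Choosing the penalty, and honest evaluation

`select_lambda()` picks $\lambda$ on a 100-point log-spaced grid
(descending from a data-driven $\lambda_{\max}$ over four orders of
magnitude) by stratified 5-fold cross-validated AUROC, with ties broken
toward the stronger penalty. The grid search fits the whole ridge path
per fold through glmnet, whose objective was verified numerically to
match the package solver's parametrization (after a $d/(d+1)$
penalty-rescaling correction, frozen in a test at a $10^{-3}$ coefficient
tolerance); every final fit at the selected penalty is produced by the
package's own solver.

`nested_cv_scores()` wraps this in an outer stratified 5-fold loop:
$\lambda$ is selected inside each outer training set, and each variant is
scored exactly once, by a model that never saw it. Because fold
assignment is itself a noise source, `repeated_cv_performance()` repeats
the whole procedure (30 times by default) and reports the mean AUROC and
mean average precision.

`estimate_coefficients()` reuses the machinery to quantify coefficient
uncertainty: 5-fold splitting repeated 10 times yields 50 training
splits, one fitted coefficient vector each; the elementwise mean
$\beta^{(i)}$ and standard deviation $\gamma^{(i)}$ over the archive are
the disease's coefficient estimate. $\lambda$ is re-selected on every
split (strict nesting); a fixed `lambda_grid` can be supplied to share
the grid across splits.

## Benchmark construction

`filter_noncoding()` and `apply_qc_filters()` reduce a GWAS-Catalog-style
association table to non-coding variants with MAF $\ge$ 1% outside the
extended MHC (default hg19 chr6:28,477,797–33,448,354 — the paper-style
HLA exclusion region is configurable since conventions differ).
`propagate_annotations()` propagates variant sets from child to parent
terms through an ontology DAG (terms gain their descendants' variants),
and `select_terms()` keeps terms with at least 100 annotated variants.
`assign_ld_blocks()` groups variants into LD blocks — connected
components of the pairwise $r^2 \ge 0.5$ graph, the simplest closure
consistent with "grouping" — and marks the minimum-p-value variant per
block as its representative (p ties broken by lexicographic id, for
determinism).

`match_controls()` draws up to ten control variants per positive under
four strategies: uniform (`random`), TSS-distance quantile bins (`tss`,
50 equal-count bins), and SNPsnap-style tolerance matching on MAF, gene
density, TSS distance and LD-partner count (`snpsnap`, tolerances
5%/50%/20%/50%) or on TSS distance only (`snpsnap_tss`; the "10,000%"
tolerances are represented as 100). Deviations are relative to the
positive's attribute value (SNPsnap convention); a zero-valued attribute
must be matched exactly, which guards the division. Controls are globally
unique: positives claim controls greedily in a seeded random order, since
no claim order is canonically defined. Positives with no eligible
candidate are dropped and recorded, and an audit table of per-pair
deviations is returned so the tolerance guarantees can be checked
mechanically.

`temporal_split()` builds the time-based evaluation design: variants
dated after a cutoff form the test pool, minus any variant within 1 kb of
a training variant on the same chromosome. Undated variants go to the
training side — never to the test side, so missing metadata cannot
contaminate the evaluation. The per-term minimum counts are parameters
(`min_train = 20`, `min_test = 50` by default) because the two natural
conventions (which side needs 20 vs 50) both appear in practice.

`select_holdout_chromosomes()` provides the chromosome-holdout design: it
maximizes $\sum_i c_i x_i$ with $c_i = w^+_i - |w^+_i - w^-_i|$ over
binary indicators, subject to the held-out positive mass not exceeding a
budget (default 20%). The printed form of this program is sometimes
stated with a zero right-hand side, which would force the empty set; the
budget is therefore an explicit parameter. The program is a 0/1 knapsack
and is solved exactly by branch and bound (no LP library is required);
tests certify the optimum against exhaustive enumeration.

## Metrics and paired comparisons

`compute_metrics()` reports AUROC (rank statistic, midranks under ties)
and average precision (step-wise, non-interpolated integration of the
precision–recall curve, thresholds at distinct score values so tied
scores enter simultaneously — the same convention as scikit-learn, stated
here because AP conventions differ across packages). Method comparisons
use `bootstrap_subsample_performance()` — 30 stratified 90% subsamples
*without* replacement, with the same index sets delivered to every method
so records are paired — and `pairwise_compare()`, a two-sided Wilcoxon
signed-rank test with zero differences dropped, an exact null for $n \le
25$ without tied ranks, full sign-flip enumeration for small tied
samples, and a tie- and continuity-corrected normal approximation
otherwise. An outcome is a tie when $p \ge 0.05$; otherwise the method
with the larger mean wins. `tally_comparisons()` aggregates wins, losses
and ties and the winning percentage $100 \cdot
\text{wins}/(\text{wins}+\text{losses})$, rounded to the nearest integer.

## Disease similarity from coefficient vectors

Two diseases are similar when the same tissues carry their models. The
similarity of diseases $i, j$ is the signed squared *weighted* Pearson
correlation of $\beta^{(i)}$ and $\beta^{(j)}$ with per-tissue weights
$w_k = 1 / (s^i_k s^j_k)$, where $s_k = \frac34 \gamma_k + \frac14 m$
shrinks each coefficient standard deviation toward $m$, the 25% quantile
(linear interpolation — the convention matters and is documented) of all
standard deviations pooled across diseases and tissues. Although the
underlying quantity is described as a weighted regression of one
coefficient vector on the other — an asymmetric operation — the weights
are symmetric and the weighted $r^2$ equals the squared weighted
correlation, so the symmetric form is implemented; it removes the
ordering ambiguity while computing the same number, and with constant
weights it reduces exactly to $\mathrm{sign}(r)\, r^2$ of the plain
Pearson correlation (asserted to $10^{-12}$). Pooling $m$ across all
diseases is the default; per-pair pooling is available behind
`pool = "pair"`.

Downstream: `cluster_diseases()` cuts an average-linkage hierarchical
clustering of the distance $1 - s_m$ (linkage is configurable; average
linkage is the default choice for a similarity without metric
guarantees), `normalize_coefficients()` maps each disease's coefficients
to $[0,1]$ by $(x - x_{\min})/x_{95}$ capped at 1 above the 95% quantile
(and clamped below, since a negative minimum can push sub-quantile values
above 1), `cluster_specific_tissues()` runs one-sided rank-sum tests of
each cluster against all other diseases (the described comparison group
is grammatically ambiguous; cluster-vs-rest is the default and a
cluster-vs-next-highest-cluster variant sits behind
`comparison = "next_highest"`), and `assign_tissue_cluster()` assigns
each tissue to the cluster with the highest median normalized
coefficient, flagging exact ties. `combine_genetic_correlation()`
combines per-study genetic correlations into a disease-pair value with
sample-size-proportional study weights, renormalizing when study pairs
lack an estimate.

## The synthetic generator

`simulate_dataset()` is first-class, tested code, not a fixture dump. It
emulates the benchmark's structure: per-variant tissue scores are
independent Beta(1, 4) draws — right-skewed and bounded like
accessibility signal, mostly closed with an open tail — and labels are
Bernoulli draws from the logistic aggregation model with a planted
support (default: 3 tissues at effect size 3 on the logit scale, roughly
a 20-fold odds span per tissue, a strong but realistic open-chromatin
enrichment) plus a unit weight on the tissue mean. The intercept is
calibrated by root finding so the expected positive fraction equals
$1/(1 + 10)$, matching the 1:10 matched-control design; variants receive
chromosomes, positions, dates around a temporal cutoff, and
control-matching attributes (MAF uniform on [0.01, 0.5], log-uniform TSS
distance, Poisson gene density and LD-partner counts).
`simulate_disease_collection()` shares planted supports within disease
groups and makes them disjoint across groups, so similarity-recovery
properties have a known truth; `simulate_ontology()` builds balanced
DAGs with closed-form propagated counts; `simulate_control_pool()`
guarantees (and audits at generation time) that every positive has
eligible candidates under the default matching tolerances.

What the generator does *not* emulate: LD-induced correlation between
variants' scores, correlated tissue tracks, genomic clustering of
association signal, or score distributions with point mass at zero.
Passing recovery tests therefore demonstrate correctness of the
estimation machinery under the model's own assumptions, not performance
on real epigenomes.

## Numerical choices and edge cases

* Quantiles everywhere use linear interpolation (R type 7); this affects
  the shrinkage floor $m$ and the $x_{95}$ normalization scale.
* Genomic coordinates are 1-based inclusive internally; BED/bedGraph
  exports are 0-based half-open. Track scoring uses fixed 25 bp bins,
  position $p$ mapping to bin $\lfloor (p-1)/25 \rfloor$; positions
  outside track bounds score as `NA` with a warning rather than being
  silently dropped.
* The knapsack solver admits a $10^{-12}$ capacity tolerance so
  exact-budget selections survive floating-point rounding.
* Degenerate similarity inputs (zero weighted variance) return 0 with a
  `degenerate` flag; an all-zero standard-deviation matrix is an error,
  because inverse-variance weights would be undefined.
* All randomized procedures take explicit seeds; child seeds are derived
  by integer sampling so concurrent procedures (fold assignment, control
  claiming, subsample draws) use isolated streams, and repeated calls are
  bit-identical.

## Problem sizes used by the test suite

The suite regenerates everything from code. Recovery checks run at 2,000
positives + 20,000 controls with 50 tissues and a 3-tissue support;
routine unit tests use 30–100 positives with 4–12 tissues; the
random-scorer baseline is computed on 1,000 positives + 10,000 controls
(large enough that the finite-sample bias of average precision under
random ranking — about +0.006 at 100 positives — no longer distorts the
second decimal, which would otherwise read 0.10 instead of the
random-guessing expectation of 1/11 ≈ 0.09); the Monte-Carlo
AP-equals-prevalence check uses 400 positives + 4,000 controls for the
same reason.

## Known limitations

* Under pure-noise features, cross-validated AUROC selection of
  $\lambda$ is unstable: the profile is flat, and because the tissue-mean
  column is unpenalized and sign-constrained, a chance anti-correlation
  of the tissue mean with the labels can make *large* penalties look
  worse than small ones in the inner folds. One might expect noise data
  to drive the selection toward strong regularization; with this
  architecture it often does not. The guarantees that matter are tested
  instead: permuted labels give chance-level held-out performance, and
  exactly tied profiles resolve toward the stronger penalty.
* The average-precision estimator is upward-biased under random ranking
  at small positive counts (see above); per-disease AP values on small
  terms should be compared against a matched random baseline, not
  against prevalence.
* The similarity measure compares coefficient *patterns*; two diseases
  can be similar because their models fail in the same way. Model
  performance should be inspected alongside similarity.
* Hierarchical clustering of $1 - s_m$ treats a non-metric quantity as a
  dissimilarity; cluster counts are a display choice, not an inference.

```{r session, echo = FALSE}
sessionInfo()
```
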
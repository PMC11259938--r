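# dscore — disease-specific prioritization of non-coding GWAS variants

Roughly 90% of disease-associated variants found by genome-wide
association studies lie outside protein-coding sequence. Scores that rank
such variants are usually either organism-wide (one number per variant,
blind to disease context) or tissue-level (one number per variant per
tissue, leaving the user to guess the relevant tissues). `dscore`
implements the third option: it *learns*, per disease, how to aggregate
tissue-level chromatin-accessibility scores into a single
disease-specific score, using the disease's known associated variants
against matched control variants. It is aimed at statistical geneticists
and functional-genomics analysts who want to rank candidate non-coding
variants for a specific phenotype, and at anyone studying which tissues
drive a disease's regulatory architecture.

## The model

Variant *i* carries a score vector *x<sub>i</sub>* ∈ ℝ<sup>d</sup> over
*d* tissue contexts with tissue-mean *x̄<sub>i</sub>*. With labels
*y<sub>i</sub>* (1 = disease-associated, 0 = matched control), the model
is

> logit *p<sub>i</sub>* = α₀ + α·*x̄<sub>i</sub>* + β′*x<sub>i</sub>*,  α ≥ 0,

fitted by minimizing the class-weighted mean negative log-likelihood plus
a ridge penalty (λ/2)‖β‖². The tissue-mean term is unpenalized and
sign-constrained, so for large λ the model falls back to the
disease-agnostic tissue-mean baseline instead of inverting it. λ is
chosen by stratified 5-fold cross-validated AUROC on a 100-point grid;
held-out disease scores come from nested cross-validation, so no variant
is scored by a model that saw it. Repeating the 5-fold estimation 10
times yields 50 coefficient vectors per disease, whose elementwise mean
β and SD γ feed a disease–disease similarity: the signed squared weighted
Pearson correlation of two diseases' β vectors with inverse-variance
weights built from shrunken SDs (s = ¾γ + ¼m, m the pooled 25% SD
quantile).

The package also builds the surrounding benchmark machinery: non-coding
and MAF/HLA filtering, ontology propagation of variant annotations,
LD-block representatives, temporal train/test splits, four matched
control selection strategies with global-uniqueness guarantees, paired
Wilcoxon win/loss/tie comparison tables, an exact binary-programming
chromosome holdout, and a synthetic-data generator that emulates all
inputs so everything runs without external downloads.

## Worked example

```r
library(dscore)

# a synthetic benchmark: 300 positives, ten matched controls each,
# 40 tissue contexts, signal planted in tissues 3, 11 and 27
cfg <- simulation_config(n_pos = 300, d_tissues = 40,
                         planted_support = c(3, 11, 27), seed = 42)
ds <- simulate_dataset(cfg)

# disease-agnostic baseline vs disease-specific tissue weighting
baseline <- compute_metrics(tissue_mean_score(ds$X), ds$y, "tissue-mean")
cv <- nested_cv_scores(ds$X, ds$y, seed = 7)
weighted <- compute_metrics(cv$scores, ds$y, "tissue-weighted")
print(rbind(baseline, weighted), digits = 3)
#>             label auroc avg_precision
#> 1     tissue-mean 0.571         0.112
#> 2 tissue-weighted 0.724         0.229
```

The tissue-weighted score doubles the average precision of the
disease-agnostic baseline (0.229 vs 0.112; a random scorer would sit at
the prevalence, 1/11 ≈ 0.091) because it concentrates weight on the
informative tissues:

```r
est <- estimate_coefficients(ds$X, ds$y, folds = 5, repeats = 2, seed = 7)
top <- order(-abs(est$beta_mean))[1:5]
print(data.frame(tissue = names(est$beta_mean)[top],
                 beta_mean = round(est$beta_mean[top], 2),
                 beta_sd = round(est$beta_sd[top], 2)), row.names = FALSE)
#>      tissue beta_mean beta_sd
#>  tissue_003      1.93    0.38
#>  tissue_011      1.83    0.32
#>  tissue_027      1.54    0.22
#>  tissue_023     -0.58    0.21
#>  tissue_025     -0.45    0.13
```

The three planted tissues head the ranking. For an out-of-chromosome
evaluation, an exact binary program picks holdout chromosomes carrying
about 20% of the positives while preserving the class imbalance:

```r
fr <- chromosome_fractions(ds$variants$chrom, ds$y)
select_holdout_chromosomes(fr$w_plus, fr$w_minus, budget = 0.2)
#> Holdout selection: chromosomes {5, 7, 9, 17}
#>   positives held out: 19.8% (budget 20%), objective 0.1872
```

A thin command-line wrapper over the same functions ships in
`inst/cli/dscore` (subcommands `simulate`, `inventory`, `match`, `fit`,
`holdout`). The methods vignette
(`vignettes/disease-specific-scoring.Rmd`) documents the model,
parameter defaults, numerical conventions and known limitations.

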
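# nurturekit

Family-based separation of **direct** and **indirect genetic effects**
("genetic nurture") on quantitative traits, with the full supporting
workflow: simulation of nuclear-family cohorts, Mendelian imputation of
missing parental genotypes, polygenic-score construction, kinship and
ancestry handling, and the joint regression with its downstream
statistics.

## The problem and the model

A parent's genotype reaches a child's trait through two causal paths:
allele transmission, and the environment the parent builds. Classical
GWAS and polygenic risk scores (PRSs) mix the two. With genotyped (or
imputed) parents, they separate in the joint regression

```
Y_proband = δ·PRS_proband + β_m·PRS_mother + β_p·PRS_father + γ'X + ε
```

where `X` holds age, age², sex, age×sex and the leading genetic principal
components, and all traits and scores are standardized. Conditioning on
both parental scores makes `δ` the **direct genetic effect (DGE)**; the
**indirect genetic effect (IGE)** is `(β_m + β_p)/2`. The package also
reports the ratio `δ/(δ + IGE)`, its square (the fraction of
PRS-explained variance due to direct effects alone), the incremental R²
of the proband PRS, and two-sided Z-contrasts between maternal and
paternal effects and between measurement waves.

Missing parents are handled the way family-based PRS analyses do it:
their genotypes are imputed by conditional expectation under Mendelian
inheritance from phased family data — transmitted allele + allele
frequency for parent-offspring duos, IBD-conditional parental sums for
sibling pairs (a three-state hidden Markov model decodes sibling IBD),
and exact recovery of unshared haplotypes when a sibling pair comes with
one genotyped parent. Conditional-expectation imputation keeps the
regression coefficients unbiased; it costs precision, not validity.

## Worked example

```r
library(nurturekit)

cfg <- sim_config(n_variants = 300, n_families = 2000, block_len = 20, seed = 42)
bundle <- simulate_cohort(cfg)
bundle
#> cohort_bundle: 2000 families, 6022 individuals x 300 variants
#>   family categories:
#> duo_missing_father duo_missing_mother sibpair_no_parents               trio
#>                503                 98                 22               1377
#>   masked parents: 645 individuals (623 imputation units)

res <- analyze_cohort(bundle, n_pcs = 10)   # impute -> score -> standardize -> fit
res$fit
#> Joint direct/indirect genetic-effect fit (OLS)
#>   n = 2000 probands
#>   DGE  delta  =  0.279 (95% CI  0.215 -  0.343)
#>   IGE  (bm+bp)/2 =  0.023 (95% CI -0.021 -  0.068)
#>   beta_m =  0.050, beta_p = -0.003, maternal-paternal z = 1.62 (p = 0.106)
#>   ratio DGE/(IGE+DGE) = 0.922 (squared 0.851)
#>   PRS incremental R^2 = 0.0825; DGE share of it = 0.0702
```

The cohort was generated with a true direct effect of 0.2625 and true
maternal/paternal indirect effects of 0.05 (spousal PRS correlation
0.06); at n = 2000 the fit recovers the direct effect well and the IGE
within its (wide) confidence interval — recovering a 0.05 indirect
effect reliably takes the full multi-cohort averaging that
`scripts/acceptance.R` performs.

Imputation quality is assessed by masking genotyped parents in complete
trios and re-imputing them:

```r
quality <- mask_and_score(bundle, seed = 42)   # default rate: 844/2736
round(c(masked = quality$n_masked, allele_spearman = quality$mean_spearman,
        allele_pearson = quality$mean_pearson_by_variant,
        prs_correlation = quality$prs_correlation), 3)
#>          masked allele_spearman  allele_pearson prs_correlation
#>         425.000           0.688           0.708           0.730
```

The per-variant Pearson accuracy sits at its analytic value `sqrt(1/2) ≈
0.707` for per-variant (LD-free) duo imputation, and the PRS-level
correlation exceeds the rank-based allele accuracy.

An end-to-end reproducible run with persisted artifacts (phased VCF,
FAM pedigree, PRS/kinship tables, estimates JSON, manifest with hashes):

```r
run_pipeline(run_config(sim = cfg, seed = 7), "runs/demo")
```

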
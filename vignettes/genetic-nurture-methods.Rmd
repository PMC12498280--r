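---
title: "Estimating direct and indirect genetic effects in nuclear families"
author: "nurturekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating direct and indirect genetic effects in nuclear families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nurturekit)
```

## The model

Parents shape a child's trait twice over: once by transmitting alleles, and
once by building the environment the child grows up in. When the trait is
heritable and environmentally malleable, the parental genotype therefore has
a *direct* path (transmission) and an *indirect* path (nurture) to the
child's phenotype. With polygenic risk scores (PRSs) for the proband and
both parents, the two are separated by the joint regression

$$Y = \delta\, z_c + \beta_m z_m + \beta_p z_p + \gamma' X + \varepsilon,$$

where $z_c, z_m, z_p$ are the standardized proband, maternal and paternal
scores and $X$ collects age, age$^2$, sex, age$\times$sex and the leading
genetic principal components. Conditioning on both parental scores makes
$\delta$ the direct genetic effect (DGE); the indirect genetic effect (IGE,
"genetic nurture") is the average parental coefficient
$(\beta_m + \beta_p)/2$, the effect of parental genotype that is *not*
explained by transmission. Downstream summaries are the ratio
$\delta/(\delta + \mathrm{IGE})$, its square (the fraction of the
PRS-explained variance attributable to direct effects alone), two-sided
Z-contrasts between the maternal and paternal coefficients and between
measurement waves, and the incremental $R^2$ of the proband PRS over the
covariates.

`fit_joint()` implements the regression with a homoskedastic OLS covariance
(a sandwich option exists but is off by default, matching the plain linear
models the design calls for). The IGE standard error uses the full linear
combination, $\tfrac12\sqrt{V_{mm} + V_{pp} + 2V_{mp}}$; the covariance
term matters because the parental scores are correlated through the
proband's.

## What the simulator emulates

`simulate_cohort()` generates the data structure this design needs:

* **Founders** carry two haplotypes of unlinked biallelic variants drawn
  Bernoulli$(p_v)$ under Hardy-Weinberg equilibrium, with $p_v$ from a
  configurable frequency law (default uniform on $[0.05, 0.5]$).
* **Assortative mating.** Mothers and fathers are rank-matched on
  $z + \kappa\,\epsilon$ with $\kappa = \sqrt{1/\rho - 1}$, a Gaussian-copula
  calibration whose closed form makes the realized spousal PRS correlation
  converge to the target $\rho$; the defaults use $\rho = 0.06$ (BMI-like)
  with $0.17$ available as the height-like setting. Pairing is
  single-generation: one round of assortment on an equilibrium founder
  population.
* **Transmission** follows Mendel: per variant (or per block of
  `block_len` consecutive variants) a fair coin picks which parental
  haplotype is passed on. The haplotype slot convention is fixed
  throughout: slot 1 is the maternal-origin allele, slot 2 paternal.
  Blocks exist solely to give sibling pairs realistic contiguous IBD
  segments; real linkage disequilibrium is not modeled.
* **Phenotypes** follow the generative mirror of the regression:
  $Y = \delta z_c + \eta_m z_m + \eta_p z_p + \gamma'X + \varepsilon$, with
  the residual SD solved (when not given) so that $\mathrm{Var}(Y) = 1$,
  and standardization within sex strata standing in for age/sex
  standard-deviation scores.
* **Missingness** reproduces the family mix of the emulated cohort: of
  5241 families, 3608 complete trios, 1319 father-missing and 257
  mother-missing duos, and 57 sibling pairs with no genotyped parent
  (1633 imputation units in total). `family_mix()` scales these
  proportions to any cohort size.

### Default effect sizes

The defaults describe a mid-childhood BMI-like trait: IGE
$\eta_m = \eta_p = 0.05$ SD per PRS SD, and DGE $\delta = 0.2625$, the
value implied by a published ratio of $0.84$ together with an IGE of 0.05
(the corresponding DGE $R^2$ of $6.9\%$ sits inside the reported
$6.0$–$10.5\%$ band). For the oldest wave the package's acceptance script
uses $\delta = 0.324$: the ratio bound $0.88$ would imply
$\delta = 0.367$, whose DGE $R^2$ of $13.4\%$ exceeds the reported
maximum, so the calibration instead takes the $R^2$ upper bound
($0.324^2 = 10.5\%$, implied ratio $0.866$), consistent with the
observation that the PRS explains the most variance at the oldest wave.

### A disequilibrium subtlety

At assortative-mating *equilibrium* the parent-child PRS correlation is
$(1+\rho)/2$. One generation of assortment on an equilibrium founder pool
gives the child the spousal covariance without yet inflating the parental
variance, so the exact value is

$$\mathrm{cor}(z_c, z_m) = \frac{(1+\rho)/2}{\sqrt{1 + \rho/2}},$$

i.e. $0.562$ rather than $0.585$ at $\rho = 0.17$. The difference is inside
the $\pm 0.03$ calibration band the tests use, and the test suite also
checks the exact disequilibrium form; multi-generation equilibrium mating
is out of scope.

## Mendelian imputation of missing parents

All imputation is per-variant conditional expectation given the observed
family data — the property that matters downstream, because a regressor
replaced by its conditional expectation leaves OLS coefficients unbiased
(the imputation error is orthogonal to everything observed).

* **Duos** (`impute_duo()`): the allele the missing parent transmitted is
  visible on the child's corresponding haplotype once parent of origin is
  assigned (`assign_parent_of_origin()` counts Mendelian inconsistencies
  against the genotyped parent for both assignments and takes the
  smaller; ties fall back to frequency-only imputation $2p$). The
  expected dosage is $t + p$, with $p$ the in-sample allele frequency.
* **Sibling pairs without parents**: a three-state hidden Markov model
  (`infer_sib_ibd()`) decodes the number of shared parental haplotypes
  with stationary prior $(\tfrac14, \tfrac12, \tfrac14)$, adjacent-state
  transitions with per-step switch probability (default $10^{-3}$;
  $1/(2\,\texttt{block\_len})$ matches the generative switch rate of
  block-transmitted simulations), and condensed-identity emissions.
  Parents are unidentifiable here, so the parental *sum* is imputed —
  $G_1 + G_2$, $G_1 + G_2 - s + p$ or $G_1 + 2p$ for IBD 0/1/2 — and each
  parent scored as $S/2$. Such families cannot inform the
  maternal-paternal contrast and are flagged accordingly.
* **Sibling pairs with one genotyped parent**: both sibs' missing-parent
  haplotypes are exposed via parent-of-origin assignment; sharing is
  decided in non-overlapping 50-variant windows with a 2% mismatch
  ceiling. Unshared windows observe both parental alleles exactly;
  shared windows revert to $t + p$.

Because the imputation is per-variant (no linkage information), the
allele-level accuracy for duos has a closed form: the correlation between
$t + p$ and the true $t + u$ is $\sqrt{pq/2pq} = \sqrt{1/2} \approx 0.707$
at every frequency. LD-aware tools exceed this on real data; the package
states the analytic value openly and tests against it rather than against
cohort-specific accuracies. The rank-based (Spearman) allele accuracy sits
slightly below $\sqrt{1/2}$ under a frequency spectrum away from 0.5
because of tied grades on discrete dosages, which is why PRS-level accuracy
strictly exceeds it — the aggregation property the masking experiment
(`mask_and_score()`, default masking rate $844/2736 \approx 31\%$ of
trios) reports.

### Standardization of imputed scores

Imputed expected scores have shrunken variance
($\mathrm{Var}\,E[X\mid Z] \le \mathrm{Var}\,X$). Standardizing each role
against the *observed* individuals' mean and SD, and applying that affine
map to the imputed members too (`standardize_roles(reference =
"observed")`), keeps all three regressors on the per-true-PRS-SD scale, so
the conditional-expectation argument above goes through and the pooled
coefficient stays unbiased. Standardizing imputed scores to unit variance
(`reference = "all"`) would shrink the parental coefficients by the
mixture-SD ratio; both options are exposed.

## Supporting machinery

* **QC filters** use the stated rules: palindromic (A/T, C/G) variants
  with alternate-allele frequency in $[0.40, 0.60]$ removed; minor-allele
  frequency $\ge 0.01$ (inclusive, applied to $\min(p, 1-p)$); batch
  association tested per variant by an allelic $2\times2$ chi-square
  without continuity correction, removal at $p < 10^{-5}$; optional HWE
  ($p < 10^{-7}$) and call-rate ($< 97.5\%$) filters default off because
  simulated founders satisfy them by construction. The filters commute.
* **Kinship** is the symmetric KING-robust estimator
  $\phi = (N_{Aa,Aa} - 2N_{AA,aa})/(N_{Aa}^{(i)} + N_{Aa}^{(j)})$ with
  classes at $0.354/0.177/0.0884/0.0442$ (first-degree bound inclusive;
  third-degree bound $2^{-9/2}$, the conventional value, since only the
  degree is specified). Parent-offspring versus full siblings is split by
  the opposite-homozygote rate ($\le 10^{-3}$), a choice this package
  makes explicitly. `prune_independent()` removes relatives greedily
  (most-connected first, ties by id order) — deterministic and fast,
  occasionally removing one more sample than the optimum.
* **Ancestry gate**: centroid of the reference panel on PC1/PC2, radius =
  the maximum reference distance, samples outside excluded (boundary
  inclusive). PCs come from frequency-standardized dosages after greedy
  $r^2 > 0.2$ pruning in 50 kb windows.

## Numerical choices and degenerate inputs

Zero-probability emissions at every state abort with the offending
variant named (corrupt input, e.g. opposite homozygotes everywhere).
Rank-deficient regression designs and zero-variance standardizations are
hard errors naming the culprit. The DGE/(IGE+DGE) ratio is flagged
unstable when the denominator is within four combined standard errors of
zero. The forward-backward pass is scaled per step, verified against
brute-force path enumeration to $10^{-10}$. All stochastic stages draw
seeds deterministically from a global seed and the stage name
(`derive_seed()`), so a pipeline run (`run_pipeline()`) is bit-reproducible
and every stage can be re-run from its persisted inputs.

## Problem sizes

The packaged checks run at desk scale by choice: 250 (tests: 40–1000)
unlinked variants, cohorts of 3757 and 3226 families matching the two
analysis waves, 200 replicate cohorts for recovery studies, 20-variant
transmission blocks with HMM switch probability $1/40$. PRS granularity,
not variant count, is what the estimates respond to, and recovery results
were indistinguishable at larger variant counts.

## What passing tests do and do not show

The simulator reproduces the statistical skeleton the estimator relies on
— Mendelian transmission, spousal PRS correlation, the family-category
mix, conditional-expectation imputation — so green tests show the
estimator and imputation machinery are correct *under the stated model*.
They do not show robustness to linkage disequilibrium, genotyping error,
population structure beyond a single homogeneous pool, multi-generation
assortment, or indirect effects that differ between environments, and the
cohort-specific accuracy figures of LD-aware imputation are explicitly not
targeted. The between-wave Z-test treats waves as independent; with
overlapping probands it is anticonservative, a property of the procedure
itself that the test suite demonstrates rather than hides.
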
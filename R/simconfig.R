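#' Family-category mix for a simulated cohort
#'
#' Proportions of the five supported nuclear-family configurations:
#' complete trios, duos missing the father, duos missing the mother,
#' sibling pairs with no genotyped parent, and sibling pairs with one
#' genotyped parent. The default reproduces the family structure of the
#' cohort the package emulates: 3608 trios, 1319 father-missing duos,
#' 257 mother-missing duos and 57 parent-less sibling pairs out of 5241
#' families, so masking at these proportions yields 1633 imputed parental
#' genotypes (one imputation unit per duo, one parental-sum unit per
#' parent-less sibling pair).
#'
#' @param trio,duo_missing_father,duo_missing_mother,sibpair_no_parents,sibpair_one_parent
#'   Non-negative weights; they are normalized to proportions.
#' @return A named numeric vector of proportions summing to 1.
#' @export
#' @examples
#' family_mix()                 # cohort-style mix
#' family_mix(trio = 1, duo_missing_father = 0,
#'            duo_missing_mother = 0, sibpair_no_parents = 0)
family_mix <- function(trio = 3608, duo_missing_father = 1319,
                       duo_missing_mother = 257, sibpair_no_parents = 57,
                       sibpair_one_parent = 0) {
  mix <- c(trio = trio, duo_missing_father = duo_missing_father,
           duo_missing_mother = duo_missing_mother,
           sibpair_no_parents = sibpair_no_parents,
           sibpair_one_parent = sibpair_one_parent)
  if (any(!is.finite(mix)) || any(mix < 0)) stopf("family mix weights must be finite and non-negative")
  if (sum(mix) <= 0) stopf("family mix must have positive total weight")
  mix / sum(mix)
}

#' Simulation configuration
#'
#' Collects every generative parameter of the cohort simulator. The defaults
#' describe a BMI-like trait at the mid-childhood wave: direct effect
#' `delta = 0.2625` and maternal/paternal indirect effects of 0.05 per PRS
#' standard deviation (their ratio delta/(delta + IGE) is 0.84), spousal
#' PRS correlation `rho_pp = 0.06`, and the family-category mix of
#' [family_mix()].
#'
#' @param n_variants Number of unlinked biallelic variants.
#' @param maf_law Allele-frequency law for the alternate allele, either
#'   `list(dist = "uniform", min, max)` (bounds inside `[0.01, 0.99]`) or
#'   `list(dist = "fixed", value)`.
#' @param n_families Number of nuclear families (one phenotyped proband each).
#' @param mix Family-category proportions, see [family_mix()].
#' @param rho_pp Target mother-father PRS correlation in `[0, 1)` induced by
#'   assortative mating.
#' @param delta Direct genetic effect, phenotype SD per proband-PRS SD.
#' @param eta_m,eta_p Maternal and paternal indirect (nurture) effects,
#'   phenotype SD per parental-PRS SD.
#' @param sigma_eps Residual SD of the phenotype before standardization;
#'   `NULL` solves for the value that makes the phenotype variance 1 given
#'   the genetic and covariate effects.
#' @param beta_age,beta_sex Covariate effects (per year of age, and for
#'   female vs male) entering the generative phenotype model.
#' @param age_range Length-2 numeric, uniform age range in years.
#' @param p_female Proportion of female probands.
#' @param n_sibs Number of genotyped children in sibling-pair families
#'   (the first is the proband).
#' @param block_len Number of consecutive variants co-transmitted as one
#'   block during meiosis. `1` simulates fully unlinked variants; larger
#'   values create sibling IBD segments without modeling real linkage
#'   disequilibrium.
#' @param weight_sd SD of the synthetic Normal per-allele weights.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_variants = 200, n_families = 100, seed = 1)
#' cfg$mix
sim_config <- function(n_variants = 1000,
                       maf_law = list(dist = "uniform", min = 0.05, max = 0.5),
                       n_families = 5241,
                       mix = family_mix(),
                       rho_pp = 0.06,
                       delta = 0.2625,
                       eta_m = 0.05,
                       eta_p = 0.05,
                       sigma_eps = NULL,
                       beta_age = 0.02,
                       beta_sex = 0.1,
                       age_range = c(9.6, 9.9),
                       p_female = 0.494,
                       n_sibs = 2,
                       block_len = 1,
                       weight_sd = 1,
                       seed = 1L) {
  if (!is.numeric(n_variants) || n_variants < 1) stopf("n_variants must be >= 1")
  validate_maf_law(maf_law)
  if (n_families < 1) stopf("n_families must be >= 1")
  mix <- family_mix(mix[["trio"]], mix[["duo_missing_father"]],
                    mix[["duo_missing_mother"]], mix[["sibpair_no_parents"]],
                    mix[["sibpair_one_parent"]])
  if (!is.numeric(rho_pp) || rho_pp < 0 || rho_pp >= 1) {
    stopf("rho_pp must lie in [0, 1), got %s", format(rho_pp))
  }
  if (!is.null(sigma_eps) && (!is.finite(sigma_eps) || sigma_eps <= 0)) {
    stopf("sigma_eps must be > 0")
  }
  if (n_sibs < 2) stopf("sibling families need n_sibs >= 2")
  if (block_len < 1) stopf("block_len must be >= 1")
  cfg <- list(n_variants = as.integer(n_variants), maf_law = maf_law,
              n_families = as.integer(n_families), mix = mix, rho_pp = rho_pp,
              delta = delta, eta_m = eta_m, eta_p = eta_p,
              sigma_eps = sigma_eps, beta_age = beta_age, beta_sex = beta_sex,
              age_range = age_range, p_female = p_female,
              n_sibs = as.integer(n_sibs), block_len = as.integer(block_len),
              weight_sd = weight_sd, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

validate_maf_law <- function(law) {
  if (!is.list(law) || is.null(law$dist)) stopf("maf_law must be a list with a 'dist' element")
  if (law$dist == "uniform") {
    if (!all(is.finite(c(law$min, law$max)))) stopf("maf_law bounds must be finite")
    if (law$min < 0.01 || law$max > 0.99 || law$min > law$max) {
      stopf("maf_law uniform bounds must satisfy 0.01 <= min <= max <= 0.99")
    }
  } else if (law$dist == "fixed") {
    if (!is.finite(law$value) || law$value < 0 || law$value > 1) {
      stopf("maf_law fixed value must lie in [0, 1]")
    }
  } else {
    stopf("unsupported maf_law dist '%s'", law$dist)
  }
  invisible(law)
}

# expected value of the alternate-allele frequency under the law
maf_law_mean <- function(law) {
  switch(law$dist,
         uniform = (law$min + law$max) / 2,
         fixed = law$value)
}

draw_maf <- function(law, n) {
  switch(law$dist,
         uniform = stats::runif(n, law$min, law$max),
         fixed = rep(law$value, n))
}

#' Residual SD that standardizes the generative phenotype
#'
#' Solves `Var(Y) = 1` for the residual SD given the generative direct and
#' indirect effects, the spousal PRS correlation (which fixes the
#' parent-child PRS correlation at `(1 + rho)/2`), and the covariate
#' effects.
#'
#' @param config A [sim_config()].
#' @return Positive residual SD.
#' @export
#' @examples
#' implied_sigma_eps(sim_config())
implied_sigma_eps <- function(config) {
  r_cp <- (1 + config$rho_pp) / 2
  g <- config$delta^2 + config$eta_m^2 + config$eta_p^2 +
    2 * config$delta * (config$eta_m + config$eta_p) * r_cp +
    2 * config$eta_m * config$eta_p * config$rho_pp
  v_cov <- config$beta_age^2 * diff(config$age_range)^2 / 12 +
    config$beta_sex^2 * config$p_female * (1 - config$p_female)
  v <- 1 - g - v_cov
  if (v <= 0) {
    stopf("generative effects already exceed unit variance (genetic %0.3f + covariate %0.3f); set sigma_eps explicitly",
          g, v_cov)
  }
  sqrt(v)
}

# integer family counts per category by largest-remainder apportionment
resolve_family_counts <- function(n_families, mix) {
  raw <- mix * n_families
  counts <- floor(raw)
  rem <- n_families - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(mix))
}
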
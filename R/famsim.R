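#' Draw founder haplotypes under Hardy-Weinberg equilibrium
#'
#' Alternate-allele frequencies are drawn once per variant from the
#' configured frequency law; founder alleles are then independent
#' Bernoulli(p) per haplotype. The realized in-sample frequency is stored in
#' the variant table (`alt_freq`) next to the law draw (`alt_freq_law`),
#' because downstream imputation falls back on in-sample frequencies.
#'
#' @param config A [sim_config()].
#' @param n Number of founders to draw.
#' @param ids Optional character ids (default `I000001`, ...).
#' @param variants Optional pre-built variant table; if `NULL` a new one is
#'   generated from `config`.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as when called from [simulate_cohort()]).
#' @return A [haplotype_panel()].
#' @export
#' @examples
#' p <- draw_founders(sim_config(n_variants = 10), n = 4, seed = 1)
#' dosages(p)
draw_founders <- function(config, n, ids = NULL, variants = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 1) stopf("need at least one founder")
  if (is.null(variants)) variants <- make_variant_table(config)
  v <- nrow(variants)
  p <- variants$alt_freq_law
  mat <- matrix(stats::rbinom(n * v, 1L, rep(p, each = n)), nrow = n)
  pat <- matrix(stats::rbinom(n * v, 1L, rep(p, each = n)), nrow = n)
  ids <- ids %||% sprintf("I%06d", seq_len(n))
  variants$alt_freq <- colMeans(mat + pat) / 2
  haplotype_panel(mat, pat, variants, ids)
}

make_variant_table <- function(config) {
  v <- config$n_variants
  p <- draw_maf(config$maf_law, v)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, v, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(variant_id = sprintf("v%06d", seq_len(v)),
             chrom = "1",
             pos = seq_len(v) * 5000L,
             ref = ref, alt = unname(alt),
             alt_freq = p, alt_freq_law = p,
             stringsAsFactors = FALSE)
}

#' Pair mothers and fathers to a target spousal PRS correlation
#'
#' Assortative mating is emulated by Gaussian-copula rank matching: each
#' parent receives a pairing key `z + kappa * noise`, where `z` is the
#' standardized PRS and `kappa = sqrt(1/rho - 1)`; sorting both sexes by
#' their keys and matching ranks yields a realized mother-father PRS
#' correlation of approximately `rho_pp`. `rho_pp = 0` pairs at random.
#' This is single-generation (disequilibrium) assortment.
#'
#' @param score_m,score_f Numeric raw PRS vectors of equal length for the
#'   designated mothers and fathers.
#' @param rho_pp Target spousal PRS correlation in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Integer permutation `perm` such that mother `i` is paired with
#'   father `perm[i]`.
#' @export
#' @examples
#' set.seed(1)
#' zm <- rnorm(500); zf <- rnorm(500)
#' perm <- pair_mates(zm, zf, rho_pp = 0.17)
#' cor(zm, zf[perm])
pair_mates <- function(score_m, score_f, rho_pp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(score_m)
  if (length(score_f) != n) stopf("equal numbers of mothers and fathers required")
  if (rho_pp < 0 || rho_pp >= 1) stopf("rho_pp must lie in [0, 1)")
  if (rho_pp == 0) return(sample.int(n))
  kappa <- sqrt(1 / rho_pp - 1)
  key_m <- as.numeric(scale(score_m)) + kappa * stats::rnorm(n)
  key_f <- as.numeric(scale(score_f)) + kappa * stats::rnorm(n)
  # ties broken by index order via stable ranking
  ord_m <- order(key_m, seq_len(n))
  ord_f <- order(key_f, seq_len(n))
  perm <- integer(n)
  perm[ord_m] <- ord_f
  perm
}

# 0/1 coin matrix, constant within transmission blocks
draw_block_coins <- function(n, v, block_len) {
  nb <- ceiling(v / block_len)
  coins <- matrix(stats::rbinom(n * nb, 1L, 0.5), nrow = n)
  if (block_len == 1L) return(coins)
  coins[, rep(seq_len(nb), each = block_len)[seq_len(v)], drop = FALSE]
}

#' Transmit haplotypes from paired parents to one offspring each
#'
#' For every variant the offspring's maternal-slot allele is a fair coin
#' choice between the mother's two alleles, and likewise for the paternal
#' slot; with `block_len > 1` the coin is shared by consecutive variants so
#' that siblings show contiguous IBD segments. Row `i` of both parent panels
#' must belong to the same family.
#'
#' @param mothers,fathers [haplotype_panel()]s with identical variant tables
#'   and one row per family.
#' @param block_len Co-transmission block length (see [sim_config()]).
#' @param ids Offspring ids.
#' @param seed Optional integer seed.
#' @return A [haplotype_panel()] of offspring (slot `mat` = maternal origin).
#' @export
transmit <- function(mothers, fathers, block_len = 1L, ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(mothers, "haplotype_panel"), inherits(fathers, "haplotype_panel"))
  n <- nrow(mothers$mat); v <- ncol(mothers$mat)
  if (nrow(fathers$mat) != n || ncol(fathers$mat) != v) {
    stopf("mother and father panels must have matching dimensions")
  }
  cm <- draw_block_coins(n, v, block_len)
  cp <- draw_block_coins(n, v, block_len)
  child_mat <- cm * mothers$mat + (1L - cm) * mothers$pat
  child_pat <- cp * fathers$mat + (1L - cp) * fathers$pat
  ids <- ids %||% sprintf("O%06d", seq_len(n))
  haplotype_panel(child_mat, child_pat, mothers$variants, ids)
}

#' Generate proband phenotypes from the nurture model
#'
#' `Y = delta z_c + eta_m z_m + eta_p z_p + beta_age (age - mean age) +
#' beta_sex female + eps`, with `eps ~ Normal(0, sigma_eps^2)`; the result is
#' then standardized to mean 0, SD 1. Standardization within sex strata
#' (`"by_sex"`, the default) plays the role of an age/sex standard-deviation
#' score; `"overall"` standardizes the pooled sample, `"none"` returns the
#' raw scale. Families with a missing PRS in any role are excluded (NA
#' phenotype) with a message.
#'
#' @param z_c,z_m,z_p Standardized proband, maternal, paternal PRS vectors.
#' @param config A [sim_config()] carrying the effect sizes.
#' @param age,sex Optional covariate vectors (sex coded 1 = female, 0 =
#'   male); drawn from the configured laws when `NULL`.
#' @param standardize One of `"by_sex"`, `"overall"`, `"none"`.
#' @param seed Optional integer seed.
#' @return `data.frame(y, age, sex)`, one row per family.
#' @export
make_phenotypes <- function(z_c, z_m, z_p, config, age = NULL, sex = NULL,
                            standardize = c("by_sex", "overall", "none"),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  standardize <- match.arg(standardize)
  n <- length(z_c)
  stopifnot(length(z_m) == n, length(z_p) == n)
  age <- age %||% stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- sex %||% stats::rbinom(n, 1L, config$p_female)
  sigma <- config$sigma_eps %||% implied_sigma_eps(config)
  ok <- !(is.na(z_c) | is.na(z_m) | is.na(z_p))
  if (any(!ok)) message(sprintf("excluding %d families with missing PRS from phenotype generation", sum(!ok)))
  y <- rep(NA_real_, n)
  y[ok] <- config$delta * z_c[ok] + config$eta_m * z_m[ok] + config$eta_p * z_p[ok] +
    config$beta_age * (age[ok] - mean(config$age_range)) +
    config$beta_sex * sex[ok] +
    stats::rnorm(sum(ok), 0, sigma)
  if (standardize == "overall") {
    y[ok] <- (y[ok] - mean(y[ok])) / sd_strict(y[ok], "phenotype")
  } else if (standardize == "by_sex") {
    for (s in unique(sex[ok])) {
      i <- ok & sex == s
      y[i] <- (y[i] - mean(y[i])) / sd_strict(y[i], "phenotype stratum")
    }
  }
  data.frame(y = y, age = age, sex = sex)
}

#' Mask parental genotypes according to the family-category mix
#'
#' Parents flagged missing by their family's category are fully masked
#' (both haplotype slots set to `NA`): father-missing duos and one-parent
#' sibling families lose the father, mother-missing duos the mother, and
#' parent-less sibling-pair families both parents. The unmasked truth is
#' kept by the caller ([simulate_cohort()] stores it as `truth_panel`).
#'
#' @param panel A [haplotype_panel()] covering all family members.
#' @param pedigree Pedigree `data.frame` with columns `id`, `family_id`,
#'   `role` and `category` (as built by [simulate_cohort()]).
#' @param mix Optional [family_mix()]; if supplied, categories are
#'   re-assigned at random among structurally compatible families (sibling
#'   categories require families with at least two children) before
#'   masking. An error is raised if the mix requests more sibling families
#'   than exist.
#' @param seed Optional integer seed for the re-assignment.
#' @return List with elements `panel` (masked), `mask` (`data.frame` of
#'   `id`, `family_id`, `role`, `category`, `masked`), `counts`
#'   (`individuals` masked and `units`, the number of imputation units:
#'   one per duo or one-parent sibling family, one parental-sum unit per
#'   parent-less sibling family), and `pedigree` (with final categories).
#' @export
apply_missingness <- function(panel, pedigree, mix = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- pedigree
  if (!is.null(mix)) {
    fams <- unique(ped$family_id)
    n_children <- tapply(ped$role %in% c("proband", "sib"), ped$family_id, sum)[fams]
    counts <- resolve_family_counts(length(fams), mix)
    sib_cats <- c("sibpair_no_parents", "sibpair_one_parent")
    n_sib_fams <- sum(counts[sib_cats])
    eligible <- fams[n_children >= 2]
    if (n_sib_fams > length(eligible)) {
      stopf("mix requests %d sibling families but only %d families have >= 2 genotyped children",
            n_sib_fams, length(eligible))
    }
    assign <- stats::setNames(rep(NA_character_, length(fams)), fams)
    sib_pick <- sample(eligible, n_sib_fams)
    assign[sib_pick] <- rep(sib_cats, counts[sib_cats])
    rest_cats <- setdiff(names(counts), sib_cats)
    assign[is.na(assign)] <- sample(rep(rest_cats, counts[rest_cats]))
    ped$category <- assign[ped$family_id]
  }
  mask_father <- ped$category %in% c("duo_missing_father", "sibpair_one_parent", "sibpair_no_parents")
  mask_mother <- ped$category %in% c("duo_missing_mother", "sibpair_no_parents")
  masked <- (ped$role == "father" & mask_father) | (ped$role == "mother" & mask_mother)
  out <- panel
  idx <- match(ped$id[masked], out$ids)
  out$mat[idx, ] <- NA_integer_
  out$pat[idx, ] <- NA_integer_
  fam_cat <- ped[!duplicated(ped$family_id), c("family_id", "category")]
  units <- sum(fam_cat$category %in% c("duo_missing_father", "duo_missing_mother",
                                       "sibpair_no_parents", "sibpair_one_parent"))
  list(panel = out,
       mask = data.frame(id = ped$id, family_id = ped$family_id, role = ped$role,
                         category = ped$category, masked = masked,
                         stringsAsFactors = FALSE),
       counts = list(individuals = sum(masked), units = units),
       pedigree = ped)
}

#' Simulate a complete family cohort
#'
#' Runs the whole generative model: founder haplotypes under HWE,
#' assortative pairing of mothers and fathers, Mendelian transmission to
#' one or two children per family, synthetic Normal variant weights, true
#' PRS values standardized within role, nurture-model phenotypes for the
#' probands, and masking of parental genotypes according to the family mix.
#' The result is a self-contained bundle holding both the masked panel (what
#' an analyst would see) and the truth needed for evaluation.
#'
#' @param config A [sim_config()].
#' @return An object of class `cohort_bundle`: list with `config`,
#'   `variants`, `weights`, `panel` (masked), `truth_panel`, `pedigree`,
#'   `phenotypes` (per proband), `truth` (true raw and standardized PRS per
#'   family plus generative parameters), `mask` and `mask_counts`.
#' @export
#' @examples
#' b <- simulate_cohort(sim_config(n_variants = 50, n_families = 40, seed = 7))
#' b$mask_counts
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_families
  counts <- resolve_family_counts(nf, config$mix)
  fam_ids <- sprintf("F%05d", seq_len(nf))
  category <- rep(names(counts), counts)

  variants <- make_variant_table(config)
  weights <- make_weights(variants, sd = config$weight_sd)

  mothers <- draw_founders(config, nf, ids = paste0(fam_ids, "_M"), variants = variants)
  variants <- mothers$variants  # carries realized founder frequency
  fathers <- draw_founders(config, nf, ids = paste0("tmp_", seq_len(nf)), variants = variants)
  # in-sample frequency over all founders
  variants$alt_freq <- (mothers$variants$alt_freq + colMeans(dosages(fathers)) / 2) / 2
  mothers$variants <- fathers$variants <- variants

  raw_m <- score_prs(dosages(mothers), weights, variants)
  raw_f <- score_prs(dosages(fathers), weights, variants)
  perm <- pair_mates(raw_m, raw_f, config$rho_pp)
  fathers <- haplotype_panel(fathers$mat[perm, , drop = FALSE],
                             fathers$pat[perm, , drop = FALSE],
                             variants, paste0(fam_ids, "_P"))
  raw_f <- raw_f[perm]

  child1 <- transmit(mothers, fathers, config$block_len, ids = paste0(fam_ids, "_C1"))
  sib_fam <- category %in% c("sibpair_no_parents", "sibpair_one_parent")
  extra <- list()
  if (any(sib_fam)) {
    m_s <- haplotype_panel(mothers$mat[sib_fam, , drop = FALSE], mothers$pat[sib_fam, , drop = FALSE],
                           variants, mothers$ids[sib_fam])
    f_s <- haplotype_panel(fathers$mat[sib_fam, , drop = FALSE], fathers$pat[sib_fam, , drop = FALSE],
                           variants, fathers$ids[sib_fam])
    for (k in seq_len(config$n_sibs - 1L)) {
      extra[[k]] <- transmit(m_s, f_s, config$block_len,
                             ids = sprintf("%s_C%d", fam_ids[sib_fam], k + 1L))
    }
  }

  raw_c <- score_prs(dosages(child1), weights, variants)
  z <- function(x) (x - mean(x)) / sd_strict(x, "PRS")
  truth <- data.frame(family_id = fam_ids, category = category,
                      raw_c = raw_c, raw_m = raw_m, raw_p = raw_f,
                      z_c = z(raw_c), z_m = z(raw_m), z_p = z(raw_f),
                      stringsAsFactors = FALSE)

  pheno <- make_phenotypes(truth$z_c, truth$z_m, truth$z_p, config)
  pheno <- data.frame(family_id = fam_ids, id = child1$ids, pheno,
                      stringsAsFactors = FALSE)

  ped <- rbind(
    data.frame(family_id = fam_ids, id = mothers$ids, father_id = "0", mother_id = "0",
               sex = 2L, role = "mother", category = category, stringsAsFactors = FALSE),
    data.frame(family_id = fam_ids, id = fathers$ids, father_id = "0", mother_id = "0",
               sex = 1L, role = "father", category = category, stringsAsFactors = FALSE),
    data.frame(family_id = fam_ids, id = child1$ids, father_id = fathers$ids,
               mother_id = mothers$ids, sex = ifelse(pheno$sex == 1L, 2L, 1L),
               role = "proband", category = category, stringsAsFactors = FALSE))
  for (k in seq_along(extra)) {
    ped <- rbind(ped, data.frame(family_id = fam_ids[sib_fam], id = extra[[k]]$ids,
                                 father_id = fathers$ids[sib_fam],
                                 mother_id = mothers$ids[sib_fam],
                                 sex = sample(1:2, sum(sib_fam), replace = TRUE),
                                 role = "sib", category = category[sib_fam],
                                 stringsAsFactors = FALSE))
  }

  truth_panel <- do.call(panel_rbind, c(list(mothers, fathers, child1), extra))
  masked <- apply_missingness(truth_panel, ped)

  structure(list(config = config, variants = variants, weights = weights,
                 panel = masked$panel, truth_panel = truth_panel,
                 pedigree = ped, phenotypes = pheno, truth = truth,
                 mask = masked$mask, mask_counts = masked$counts),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle: %d families, %d individuals x %d variants\n",
              x$config$n_families, nrow(x$panel$mat), ncol(x$panel$mat)))
  cat("  family categories:\n")
  print(table(x$truth$category))
  cat(sprintf("  masked parents: %d individuals (%d imputation units)\n",
              x$mask_counts$individuals, x$mask_counts$units))
  invisible(x)
}
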
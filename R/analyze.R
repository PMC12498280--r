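#' Full family-based analysis of a simulated cohort
#'
#' Chains the analysis stages on a `cohort_bundle`: optional variant QC
#' (palindromic and MAF filters), Mendelian imputation of masked parents,
#' PRS scoring of probands and (observed or imputed) parents, within-role
#' standardization, proband principal components, and the joint
#' direct/indirect effect regression adjusted by age, age squared, sex,
#' age x sex and the leading PCs.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param n_pcs Number of proband principal components to adjust for.
#' @param qc Apply the palindromic and MAF filters before scoring
#'   (simulated variants satisfy both by construction, so the default is
#'   off).
#' @param prune Prune probands to third-degree-unrelated before the
#'   regression (sensitivity path; quadratic in probands, intended for
#'   moderate sample sizes).
#' @param switch_prob IBD HMM switch probability passed to
#'   [impute_missing_parents()].
#' @param reference Standardization reference for [standardize_roles()].
#' @return List with `fit` (a `nurture_fit`), `data` (the regression
#'   frame), `scores` (the PRS table), `imputation` (imputation info) and
#'   `variants_used`.
#' @export
#' @examples
#' b <- simulate_cohort(sim_config(n_variants = 150, n_families = 400, seed = 3))
#' res <- analyze_cohort(b, n_pcs = 2)
#' res$fit$ige
analyze_cohort <- function(bundle, n_pcs = 10L, qc = FALSE, prune = FALSE,
                           switch_prob = NULL,
                           reference = c("observed", "all")) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  reference <- match.arg(reference)
  variants <- bundle$variants
  if (qc) {
    variants <- filter_palindromic(variants)$kept
    variants <- filter_maf(variants)$kept
  }
  weights <- bundle$weights[bundle$weights$variant_id %in% variants$variant_id, ,
                            drop = FALSE]
  fam <- bundle$truth$family_id
  dos <- dosages(bundle$panel)
  id_c <- paste0(fam, "_C1"); id_m <- paste0(fam, "_M"); id_p <- paste0(fam, "_P")

  imp <- impute_missing_parents(bundle, switch_prob)
  imputed_ids <- rownames(imp$expected) %||% character(0)

  score_role <- function(ids) {
    obs <- setdiff(ids, imputed_ids)
    raw <- stats::setNames(rep(NA_real_, length(ids)), ids)
    if (length(obs)) {
      raw[obs] <- score_prs(dos[match(obs, bundle$panel$ids), , drop = FALSE],
                            weights, bundle$variants)
    }
    imp_ids <- intersect(ids, imputed_ids)
    if (length(imp_ids)) {
      raw[imp_ids] <- score_prs(imp$expected[match(imp_ids, imputed_ids), ,
                                             drop = FALSE],
                                weights, bundle$variants)
    }
    raw
  }
  raw_c <- score_role(id_c); raw_m <- score_role(id_m); raw_p <- score_role(id_p)

  scores <- data.frame(
    id = c(id_c, id_m, id_p),
    family_id = rep(fam, 3),
    role = rep(c("proband", "mother", "father"), each = length(fam)),
    raw = c(raw_c, raw_m, raw_p),
    imputed = c(id_c, id_m, id_p) %in% imputed_ids,
    stringsAsFactors = FALSE)
  scores <- standardize_roles(scores, reference = reference)
  zs <- function(role) scores$z[scores$role == role]

  ph <- bundle$phenotypes
  data <- data.frame(y = ph$y, z_c = zs("proband"), z_m = zs("mother"),
                     z_p = zs("father"), age = ph$age, sex = ph$sex)
  if (n_pcs > 0) {
    pcs <- pca_dosages(dos[match(id_c, bundle$panel$ids),
                           bundle$variants$variant_id %in% variants$variant_id,
                           drop = FALSE], n_pcs)
    data <- cbind(data, as.data.frame(pcs))
    n_pcs <- ncol(pcs)
  }
  rownames(data) <- id_c

  if (prune) {
    kin <- kinship_pairs(dos[match(id_c, bundle$panel$ids), , drop = FALSE],
                         classify = FALSE)
    keep <- prune_independent(id_c, kin, degree = 3L)
    data <- data[rownames(data) %in% keep, , drop = FALSE]
  }

  rhs <- "age + I(age^2) + sex + age:sex"
  if (n_pcs > 0) rhs <- paste(rhs, "+", paste0("PC", seq_len(n_pcs), collapse = " + "))
  fit <- fit_joint(data, covariate_formula = stats::as.formula(paste("~", rhs)))
  list(fit = fit, data = data, scores = scores, imputation = imp,
       variants_used = variants$variant_id)
}
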
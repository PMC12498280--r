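#' Synthetic per-allele weight table
#'
#' Stands in for externally estimated GWAS/shrinkage weights: Normal(0, sd)
#' weights on a random subset of variants (default all), effect allele set
#' to the alternate allele.
#'
#' @param variants Variant table.
#' @param n_signal Number of weighted variants (default all).
#' @param sd Weight standard deviation.
#' @param seed Optional integer seed.
#' @return `data.frame(variant_id, effect_allele, weight)`.
#' @export
make_weights <- function(variants, n_signal = NULL, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_signal <- n_signal %||% nrow(variants)
  pick <- sort(sample.int(nrow(variants), n_signal))
  data.frame(variant_id = variants$variant_id[pick],
             effect_allele = variants$alt[pick],
             weight = stats::rnorm(n_signal, 0, sd),
             stringsAsFactors = FALSE)
}

#' Score a polygenic risk score from a weight table
#'
#' `PRS_i = sum_v w_v * dose_iv`, with each dosage re-oriented to the
#' effect allele: a weight whose effect allele is the reference allele
#' contributes `w * (2 - alt_dose)`. Weight rows whose variant is absent
#' from the panel, or whose effect allele matches neither panel allele,
#' are dropped with a message; more than 50% dropped is a hard error
#' (panel/weights mismatch).
#'
#' @param dosage_matrix Individuals x variants alternate-allele dosage
#'   matrix; columns either named by `variant_id` or aligned with
#'   `variants`. Fractional (imputed expected) dosages are allowed.
#' @param weights Weight table (`variant_id`, `effect_allele`, `weight`).
#' @param variants Variant table supplying `ref`/`alt` per variant.
#' @return Named numeric vector of raw scores, one per row.
#' @export
score_prs <- function(dosage_matrix, weights, variants) {
  if (anyDuplicated(weights$variant_id)) stopf("duplicate variant_id in weight table")
  idx <- match(weights$variant_id, variants$variant_id)
  found <- !is.na(idx)
  ea <- weights$effect_allele
  on_alt <- found & ea == variants$alt[idx]
  on_ref <- found & ea == variants$ref[idx]
  usable <- on_alt | on_ref
  n_drop <- sum(!usable)
  if (n_drop > 0.5 * nrow(weights)) {
    stopf("%d of %d weight-table variants failed to join the panel; panel/weights mismatch",
          n_drop, nrow(weights))
  }
  if (n_drop > 0) message(sprintf("dropping %d weight rows that do not join the panel", n_drop))
  idx <- idx[usable]
  w <- weights$weight[usable]
  sign <- ifelse(on_alt[usable], 1, -1)
  const <- sum(2 * w[sign < 0])          # from w * (2 - alt_dose)
  cols <- if (!is.null(colnames(dosage_matrix))) {
    match(variants$variant_id[idx], colnames(dosage_matrix))
  } else idx
  scores <- as.numeric(dosage_matrix[, cols, drop = FALSE] %*% (w * sign)) + const
  stats::setNames(scores, rownames(dosage_matrix))
}

#' Standardize raw PRSs within family role
#'
#' Subtracts the role mean and divides by the role SD. By default the mean
#' and SD are estimated from *observed* (non-imputed) individuals only and
#' the resulting affine map is applied to everyone in the role: imputed
#' expected scores have shrunken variance, and standardizing them against
#' the observed-score scale keeps the joint regression's coefficients on
#' the per-true-PRS-SD scale (conditional-expectation imputation then
#' leaves them unbiased). `reference = "all"` standardizes against the
#' pooled sample instead.
#'
#' @param scores `data.frame` with columns `raw`, `role` (e.g. `proband`,
#'   `mother`, `father`) and logical `imputed`.
#' @param reference `"observed"` (default) or `"all"`.
#' @return The input with a `z` column appended.
#' @export
standardize_roles <- function(scores, reference = c("observed", "all")) {
  reference <- match.arg(reference)
  stopifnot(all(c("raw", "role", "imputed") %in% names(scores)))
  scores$z <- NA_real_
  for (r in unique(scores$role)) {
    in_role <- scores$role == r
    ref <- in_role & (if (reference == "observed") !scores$imputed else TRUE)
    if (sum(ref) < 2) stopf("role '%s' needs >= 2 reference individuals to standardize", r)
    mu <- mean(scores$raw[ref])
    s <- sd_strict(scores$raw[ref], sprintf("role '%s' scores", r))
    scores$z[in_role] <- (scores$raw[in_role] - mu) / s
  }
  scores
}

#' Incremental variance explained by a PRS
#'
#' `R^2(covariates + PRS) - R^2(covariates)` from two ordinary
#' least-squares fits on complete cases. Collinear covariate columns are
#' dropped (with a warning) before fitting.
#'
#' @param y Phenotype vector.
#' @param covariates `data.frame` or matrix of covariates (may have zero
#'   columns).
#' @param prs Numeric PRS vector.
#' @return List with `delta_r2`, `r2_full`, `r2_base`.
#' @export
incremental_r2 <- function(y, covariates, prs) {
  cov_m <- if (is.null(covariates) || NCOL(covariates) == 0) {
    matrix(numeric(0), nrow = length(y), ncol = 0)
  } else as.matrix(covariates)
  keep <- stats::complete.cases(y, prs, cov_m)
  y <- y[keep]; prs <- prs[keep]
  cov_m <- cov_m[keep, , drop = FALSE]
  if (ncol(cov_m) > 0) {
    q <- qr(cbind(1, cov_m))
    if (q$rank < ncol(cov_m) + 1L) {
      drop <- setdiff(seq_len(ncol(cov_m)), q$pivot[seq_len(q$rank)] - 1L)
      drop <- drop[drop >= 1]
      warnf("dropping %d collinear covariate column(s)", length(drop))
      cov_m <- cov_m[, -drop, drop = FALSE]
    }
  }
  r2 <- function(X) {
    fit <- stats::lm.fit(cbind(1, X), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  r2_base <- if (ncol(cov_m) > 0) r2(cov_m) else 0
  r2_full <- r2(cbind(cov_m, prs))
  list(delta_r2 = max(0, r2_full - r2_base), r2_full = r2_full, r2_base = r2_base)
}
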
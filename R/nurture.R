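#' Jointly estimate direct and indirect genetic effects
#'
#' Ordinary least squares of the proband trait on the proband, maternal and
#' paternal standardized PRSs plus covariates:
#' `Y = delta z_c + beta_m z_m + beta_p z_p + gamma' X + eps`.
#' The direct genetic effect (DGE) is `delta`; the indirect genetic effect
#' (IGE, genetic nurture) is `(beta_m + beta_p)/2` with standard error
#' `sqrt(V_mm + V_pp + 2 V_mp)/2` from the homoskedastic OLS covariance.
#' Also computes the DGE/(IGE+DGE) ratio, its square, the incremental
#' variance explained by the proband PRS over the covariates, and the
#' maternal-paternal contrast.
#'
#' @param data `data.frame` with columns `y`, `z_c`, `z_m`, `z_p`; any
#'   further columns are covariates entered linearly.
#' @param covariate_formula Right-hand-side formula for the covariates
#'   (default: every extra column, linearly). Use e.g.
#'   `~ age + I(age^2) + sex + age:sex + PC1` for the standard adjustment.
#' @param vcov_type `"homoskedastic"` (default) or `"sandwich"` (HC0).
#' @return An object of class `nurture_fit` with fields `delta`, `beta_m`,
#'   `beta_p`, `vcov` (3x3), `ige`, `se_delta`, `se_ige`, `ci_delta`,
#'   `ci_ige`, `ratio`, `ratio_sq`, `ratio_unstable`, `z_mp`, `p_mp`, `n`,
#'   `delta_r2_prs`, `dge_r2`, `sigma`, and the underlying `lm` fit.
#' @export
fit_joint <- function(data, covariate_formula = NULL,
                      vcov_type = c("homoskedastic", "sandwich")) {
  vcov_type <- match.arg(vcov_type)
  need <- c("y", "z_c", "z_m", "z_p")
  if (!all(need %in% names(data))) {
    stopf("data must contain columns %s", paste(need, collapse = ", "))
  }
  covars <- setdiff(names(data), need)
  rhs <- if (is.null(covariate_formula)) {
    if (length(covars)) paste(covars, collapse = " + ") else "1"
  } else {
    paste(deparse(covariate_formula[[2]]), collapse = "")
  }
  form <- stats::as.formula(paste("y ~ z_c + z_m + z_p +", rhs))
  mf <- stats::model.frame(form, data = data, na.action = stats::na.omit)
  n <- nrow(mf)
  X <- stats::model.matrix(form, mf)
  if (n <= ncol(X) + 10L) stopf("analysis sample too small: n = %d for %d regressors", n, ncol(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("rank-deficient design; drop or recode: %s", paste(bad, collapse = ", "))
  }
  fit <- stats::lm(form, data = data, na.action = stats::na.omit)
  cf <- stats::coef(fit)
  V <- if (vcov_type == "homoskedastic") stats::vcov(fit) else hc0_vcov(fit)
  k <- c("z_c", "z_m", "z_p")
  v3 <- V[k, k]
  delta <- cf[["z_c"]]; beta_m <- cf[["z_m"]]; beta_p <- cf[["z_p"]]
  ige <- (beta_m + beta_p) / 2
  se_delta <- sqrt(v3["z_c", "z_c"])
  se_ige <- 0.5 * sqrt(v3["z_m", "z_m"] + v3["z_p", "z_p"] + 2 * v3["z_m", "z_p"])
  zcrit <- stats::qnorm(0.975)
  denom <- delta + ige
  unstable <- abs(denom) < 4 * sqrt(se_delta^2 + se_ige^2)
  # incremental variance explained by the proband PRS over the covariates
  cov_cols <- setdiff(colnames(X), c("(Intercept)", k))
  inc <- incremental_r2(mf$y, X[, cov_cols, drop = FALSE], mf$z_c)
  out <- list(delta = delta, beta_m = beta_m, beta_p = beta_p, vcov = v3,
              ige = ige, se_delta = se_delta, se_ige = se_ige,
              ci_delta = delta + c(-1, 1) * zcrit * se_delta,
              ci_ige = ige + c(-1, 1) * zcrit * se_ige,
              ratio = if (denom != 0) delta / denom else NA_real_,
              ratio_sq = if (denom != 0) (delta / denom)^2 else NA_real_,
              ratio_unstable = unstable,
              n = n, delta_r2_prs = inc$delta_r2,
              dge_r2 = if (denom != 0) (delta / denom)^2 * inc$delta_r2 else NA_real_,
              sigma = summary(fit)$sigma, vcov_type = vcov_type, lm = fit)
  cls <- contrast_mp_safe(out, data)
  out$z_mp <- cls$z; out$p_mp <- cls$p
  class(out) <- "nurture_fit"
  out
}

hc0_vcov <- function(fit) {
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit)
  bread <- solve(crossprod(X))
  meat <- crossprod(X * u)
  bread %*% meat %*% bread
}

# internal: maternal-paternal contrast that degrades to NA (instead of
# erroring) inside fit_joint when the sample cannot identify it
contrast_mp_safe <- function(fit, data) {
  v <- fit$vcov
  var_d <- v["z_m", "z_m"] + v["z_p", "z_p"] - 2 * v["z_m", "z_p"]
  if (!is.finite(var_d) || var_d <= 0) return(list(z = NA_real_, p = NA_real_))
  z <- (fit$beta_m - fit$beta_p) / sqrt(var_d)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-sided Z-test of maternal versus paternal effects
#'
#' `z = (beta_m - beta_p) / sqrt(V_mm + V_pp - 2 V_mp)` with a two-sided
#' normal p-value. Refuses when the contrast variance is degenerate, which
#' happens when every parental score in the sample comes from parental-sum
#' imputation (maternal and paternal scores constrained equal by
#' construction).
#'
#' @param fit A `nurture_fit`.
#' @return List with `z` and `p`.
#' @export
contrast_mp <- function(fit) {
  stopifnot(inherits(fit, "nurture_fit"))
  v <- fit$vcov
  var_d <- v["z_m", "z_m"] + v["z_p", "z_p"] - 2 * v["z_m", "z_p"]
  if (!is.finite(var_d) || var_d <= 1e-12) {
    stopf(paste("maternal-paternal contrast is undefined: the parental scores are",
                "collinear (e.g. an all-parent-sum-imputed sample constrains",
                "maternal and paternal scores to be equal)"))
  }
  z <- (fit$beta_m - fit$beta_p) / sqrt(var_d)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-sided Z-test of an effect between two measurement waves
#'
#' `z = (b_a - b_b) / sqrt(se_a^2 + se_b^2)`, treating the waves as
#' independent samples. When the waves share probands this understates the
#' contrast variance's covariance term and the test is anticonservative;
#' that caveat is inherent to the procedure.
#'
#' @param fit_a,fit_b `nurture_fit` objects for the two waves.
#' @param effect `"ige"` (default) or `"delta"`.
#' @return List with `z`, `p` and the two estimates.
#' @export
contrast_ages <- function(fit_a, fit_b, effect = c("ige", "delta")) {
  effect <- match.arg(effect)
  b <- c(fit_a[[effect]], fit_b[[effect]])
  se <- if (effect == "ige") c(fit_a$se_ige, fit_b$se_ige) else c(fit_a$se_delta, fit_b$se_delta)
  z <- (b[1] - b[2]) / sqrt(sum(se^2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), estimates = b)
}

#' Variance partition between direct and indirect effects
#'
#' `ratio = delta / (delta + IGE)`; its square is the fraction of the
#' PRS-explained variance attributable to direct effects alone, and
#' `dge_r2 = ratio^2 * delta_r2_prs` expresses that fraction on the
#' phenotypic-variance scale.
#'
#' @param fit A `nurture_fit`.
#' @param delta_r2_prs Incremental variance explained by the proband PRS;
#'   defaults to the value computed by [fit_joint()].
#' @return List with `ratio`, `ratio_sq`, `dge_r2` and `unstable` (flagged
#'   when `delta + IGE` is within 4 combined SEs of zero, in which case no
#'   confidence statement should be attached).
#' @export
#' @examples
#' # 0.21 / (0.21 + 0.04) = 0.84; squared ~ 0.71
variance_partition <- function(fit, delta_r2_prs = NULL) {
  stopifnot(inherits(fit, "nurture_fit"))
  denom <- fit$delta + fit$ige
  if (denom == 0) stopf("delta + IGE is exactly zero; ratio undefined")
  r <- fit$delta / denom
  dr2 <- delta_r2_prs %||% fit$delta_r2_prs
  list(ratio = r, ratio_sq = r^2, dge_r2 = r^2 * dr2,
       unstable = fit$ratio_unstable)
}

#' @export
print.nurture_fit <- function(x, ...) {
  cat("Joint direct/indirect genetic-effect fit (OLS)\n")
  cat(sprintf("  n = %d probands\n", x$n))
  cat(sprintf("  DGE  delta  = %6.3f (95%% CI %6.3f - %6.3f)\n",
              x$delta, x$ci_delta[1], x$ci_delta[2]))
  cat(sprintf("  IGE  (bm+bp)/2 = %6.3f (95%% CI %6.3f - %6.3f)\n",
              x$ige, x$ci_ige[1], x$ci_ige[2]))
  cat(sprintf("  beta_m = %6.3f, beta_p = %6.3f, maternal-paternal z = %.2f (p = %.3g)\n",
              x$beta_m, x$beta_p, x$z_mp, x$p_mp))
  cat(sprintf("  ratio DGE/(IGE+DGE) = %.3f (squared %.3f)%s\n",
              x$ratio, x$ratio_sq, if (isTRUE(x$ratio_unstable)) "  [unstable]" else ""))
  cat(sprintf("  PRS incremental R^2 = %.4f; DGE share of it = %.4f\n",
              x$delta_r2_prs, x$dge_r2))
  invisible(x)
}

#' Long-format summary of one or more fits
#'
#' Forest-plot-ready table: one row per (wave, effect) with estimate and
#' 95% CI. Pass named fits for labeled waves.
#'
#' @param ... `nurture_fit` objects, optionally named.
#' @return `data.frame(wave, effect, estimate, lo, hi, n)`.
#' @export
forest_table <- function(...) {
  fits <- list(...)
  nm <- names(fits) %||% as.character(seq_along(fits))
  nm[nm == ""] <- as.character(seq_along(fits))[nm == ""]
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    zc <- stats::qnorm(0.975)
    d_mp <- f$beta_m - f$beta_p
    se_mp <- sqrt(f$vcov["z_m", "z_m"] + f$vcov["z_p", "z_p"] -
                    2 * f$vcov["z_m", "z_p"])
    data.frame(wave = nm[i],
               effect = c("direct", "indirect", "maternal-paternal"),
               estimate = c(f$delta, f$ige, d_mp),
               lo = c(f$ci_delta[1], f$ci_ige[1], d_mp - zc * se_mp),
               hi = c(f$ci_delta[2], f$ci_ige[2], d_mp + zc * se_mp),
               n = f$n, stringsAsFactors = FALSE)
  }))
}
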
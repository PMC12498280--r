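# fit on the truth scores of a freshly simulated cohort (no imputation),
# returning the nurture_fit
fit_truth <- function(n_families, delta, eta_m, eta_p, rho = 0.06, seed = 1,
                      n_variants = 60) {
  b <- simulate_cohort(sim_config(n_variants = n_variants, n_families = n_families,
                                  mix = trio_only_mix(), rho_pp = rho,
                                  delta = delta, eta_m = eta_m, eta_p = eta_p,
                                  seed = seed))
  d <- data.frame(y = b$phenotypes$y, z_c = b$truth$z_c, z_m = b$truth$z_m,
                  z_p = b$truth$z_p, age = b$phenotypes$age,
                  sex = b$phenotypes$sex)
  fit_joint(d, covariate_formula = ~ age + I(age^2) + sex + age:sex)
}

test_that("joint regression recovers generative effects at large n", {
  f <- fit_truth(50000, delta = 0.3, eta_m = 0, eta_p = 0, rho = 0, seed = 81)
  expect_lt(abs(f$delta - 0.3), 0.01)
  expect_lt(abs(f$ige), 0.01)
  expect_equal(f$ige, (f$beta_m + f$beta_p) / 2)
  expect_equal(f$ci_ige, f$ige + c(-1, 1) * qnorm(0.975) * f$se_ige)
  expect_true(all(eigen(f$vcov, symmetric = TRUE)$values > 0))
})

test_that("pure-noise phenotypes yield null coefficients", {
  set.seed(82)
  n <- 2000
  d <- data.frame(y = rnorm(n), z_c = rnorm(n), z_m = rnorm(n), z_p = rnorm(n))
  f <- fit_joint(d)
  expect_lt(abs(f$delta), 3 * f$se_delta)
  expect_lt(abs(f$ige), 3 * f$se_ige)
})

test_that("design guards: rank deficiency and small samples are refused", {
  set.seed(83)
  n <- 200
  d <- data.frame(y = rnorm(n), z_c = rnorm(n), z_m = rnorm(n))
  d$z_p <- d$z_m                                     # parent-sum collinearity
  expect_error(fit_joint(d), "rank-deficient")
  d2 <- data.frame(y = rnorm(8), z_c = rnorm(8), z_m = rnorm(8), z_p = rnorm(8))
  expect_error(fit_joint(d2), "too small")
})

test_that("maternal-paternal contrast behaves at the null and under signal", {
  fake <- structure(list(beta_m = 0.05, beta_p = 0.05,
                         vcov = matrix(c(1, 0, 0, 0, 2, 0.5, 0, 0.5, 2) * 1e-4,
                                       3, 3, dimnames = rep(list(c("z_c", "z_m", "z_p")), 2))),
                    class = "nurture_fit")
  r <- contrast_mp(fake)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)

  degen <- fake
  degen$vcov["z_m", "z_p"] <- degen$vcov["z_m", "z_m"] <- degen$vcov["z_p", "z_p"] <- 1e-4
  expect_error(contrast_mp(degen), "parent-sum")

  # power: asymmetric nurture detected in most moderate-n replicates
  hits <- 0
  for (i in 1:10) {
    f <- fit_truth(8000, delta = 0.2, eta_m = 0.1, eta_p = 0, rho = 0,
                   seed = 830 + i)
    if (contrast_mp(f)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("between-wave contrast is null for identical fits and detects change", {
  f <- fit_truth(3000, delta = 0.25, eta_m = 0.05, eta_p = 0.05, seed = 84)
  same <- contrast_ages(f, f)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  hits <- 0
  for (i in 1:8) {
    fa <- fit_truth(8000, delta = 0.2, eta_m = 0.05, eta_p = 0.05, seed = 8400 + i)
    fb <- fit_truth(8000, delta = 0.2, eta_m = 0.15, eta_p = 0.15, seed = 8500 + i)
    if (contrast_ages(fa, fb)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 6)
})

test_that("variance partition follows the ratio identities and invariances", {
  fake <- structure(list(delta = 0.21, ige = 0.04, ratio_unstable = FALSE,
                         delta_r2_prs = 0.10), class = "nurture_fit")
  vp <- variance_partition(fake)
  expect_equal(vp$ratio, 0.84)
  expect_equal(vp$ratio_sq, 0.7056)
  expect_equal(vp$dge_r2, 0.07056)

  pure <- structure(list(delta = 0.3, ige = 0, ratio_unstable = FALSE,
                         delta_r2_prs = 0.09), class = "nurture_fit")
  expect_equal(variance_partition(pure)$ratio, 1)
  expect_equal(variance_partition(pure)$ratio_sq, 1)

  # rescaling all three PRSs by a common positive constant leaves the ratio
  set.seed(85)
  n <- 3000
  zc <- rnorm(n); zm <- rnorm(n); zp <- rnorm(n)
  y <- 0.3 * zc + 0.05 * zm + 0.05 * zp + rnorm(n)
  f1 <- fit_joint(data.frame(y = y, z_c = zc, z_m = zm, z_p = zp))
  f2 <- fit_joint(data.frame(y = y, z_c = 3 * zc, z_m = 3 * zm, z_p = 3 * zp))
  expect_equal(f1$ratio, f2$ratio, tolerance = 1e-10)
  expect_equal(f1$ratio_sq, f2$ratio_sq, tolerance = 1e-10)
})

test_that("confidence intervals attain nominal coverage over repeated cohorts", {
  reps <- 400
  hit_d <- 0; hit_i <- 0
  for (i in seq_len(reps)) {
    f <- fit_truth(1200, delta = 0.2625, eta_m = 0.05, eta_p = 0.05,
                   seed = 20000 + i, n_variants = 40)
    if (f$ci_delta[1] <= 0.2625 && 0.2625 <= f$ci_delta[2]) hit_d <- hit_d + 1
    if (f$ci_ige[1] <= 0.05 && 0.05 <= f$ci_ige[2]) hit_i <- hit_i + 1
  }
  tol <- 0.02 + 2 * sqrt(0.95 * 0.05 / reps)
  expect_lt(abs(hit_d / reps - 0.95), tol)
  expect_lt(abs(hit_i / reps - 0.95), tol)
})

test_that("imputed-mix estimates agree with complete-trio estimates in mean, with larger SE", {
  reps <- 24
  ige_mix <- numeric(reps); ige_trio <- numeric(reps)
  se_mix <- numeric(reps); se_trio <- numeric(reps)
  for (i in seq_len(reps)) {
    bm <- simulate_cohort(sim_config(n_variants = 120, n_families = 1500,
                                     block_len = 20, seed = 300 + i))
    fm <- analyze_cohort(bm, n_pcs = 0)$fit
    bt <- simulate_cohort(sim_config(n_variants = 120, n_families = 1500,
                                     mix = trio_only_mix(), block_len = 20,
                                     seed = 600 + i))
    ft <- analyze_cohort(bt, n_pcs = 0)$fit
    ige_mix[i] <- fm$ige; ige_trio[i] <- ft$ige
    se_mix[i] <- fm$se_ige; se_trio[i] <- ft$se_ige
  }
  mc_se <- sqrt(var(ige_mix) / reps + var(ige_trio) / reps)
  expect_lt(abs(mean(ige_mix) - mean(ige_trio)), 3 * mc_se)
  expect_gt(mean(se_mix), mean(se_trio))       # information loss, not bias
})

test_that("forest table mirrors the fit and prints cleanly", {
  f <- fit_truth(2000, delta = 0.25, eta_m = 0.05, eta_p = 0.05, seed = 86)
  tb <- forest_table(age9 = f)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$estimate[tb$effect == "direct"], f$delta)
  expect_equal(tb$estimate[tb$effect == "indirect"], f$ige)
  out <- capture.output(print(f))
  expect_true(any(grepl("IGE", out)))
})
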
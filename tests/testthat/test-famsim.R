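test_that("founder draws follow the frequency law and degenerate cases", {
  cfg <- sim_config(n_variants = 1000, maf_law = list(dist = "uniform", min = 0.01, max = 0.5),
                    n_families = 10, seed = 5)
  pan <- draw_founders(cfg, n = 2000, seed = 5)
  f <- pan$variants$alt_freq
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.255), 3 * se)

  cfg0 <- sim_config(n_variants = 20, maf_law = list(dist = "fixed", value = 0),
                     n_families = 10, seed = 1)
  pan0 <- draw_founders(cfg0, n = 50, seed = 1)
  expect_true(all(dosages(pan0) == 0L))

  a <- draw_founders(cfg, n = 100, seed = 99)
  b <- draw_founders(cfg, n = 100, seed = 99)
  expect_identical(a$mat, b$mat)
  expect_identical(a$pat, b$pat)
})

test_that("config validation rejects out-of-bounds parameters", {
  expect_error(sim_config(maf_law = list(dist = "uniform", min = 0.001, max = 0.5)),
               "maf_law")
  expect_error(sim_config(maf_law = list(dist = "uniform", min = 0.1, max = NaN)),
               "finite")
  expect_error(sim_config(rho_pp = 1), "rho_pp")
  expect_error(sim_config(rho_pp = -0.1), "rho_pp")
  expect_error(sim_config(sigma_eps = 0), "sigma_eps")
  expect_error(family_mix(trio = -1), "non-negative")
})

test_that("assortative pairing realizes the target spousal correlation", {
  set.seed(21)
  n <- 5000
  zm <- rnorm(n); zf <- rnorm(n)
  perm0 <- pair_mates(zm, zf, rho_pp = 0, seed = 1)
  expect_lt(abs(cor(zm, zf[perm0])), 3 / sqrt(n))
  for (rho in c(0.06, 0.17)) {
    perm <- pair_mates(zm, zf, rho_pp = rho, seed = 2)
    expect_lt(abs(cor(zm, zf[perm]) - rho), 0.03)
  }
  expect_error(pair_mates(zm, zf, rho_pp = 1.2), "rho_pp")
})

test_that("transmission is Mendelian and respects the slot convention", {
  vt <- data.frame(variant_id = c("v1", "v2"), chrom = "1", pos = c(1L, 2L),
                   ref = "A", alt = "G", alt_freq = c(0.5, 0.5))
  mom <- haplotype_panel(matrix(1L, 1, 2), matrix(1L, 1, 2), vt, "m")   # dosage 2
  dad <- haplotype_panel(matrix(0L, 1, 2), matrix(0L, 1, 2), vt, "d")   # dosage 0
  kid <- transmit(mom, dad, seed = 1)
  expect_equal(unname(dosages(kid)[1, ]), c(1L, 1L))
  expect_equal(unname(kid$mat[1, ]), c(1L, 1L))   # maternal slot carries mother's allele
  expect_equal(unname(kid$pat[1, ]), c(0L, 0L))
})

test_that("parent-offspring PRS correlation tracks (1 + rho)/2", {
  # One-generation assortment leaves the parental PRS variance at its
  # random-mating value while the child picks up the spousal covariance, so
  # the exact disequilibrium correlation is ((1+rho)/2)/sqrt(1 + rho/2);
  # it sits within 0.03 of the equilibrium identity (1+rho)/2.
  for (rho in c(0, 0.17)) {
    b <- simulate_cohort(sim_config(n_variants = 150, n_families = 20000,
                                    mix = trio_only_mix(), rho_pp = rho,
                                    seed = 31 + round(100 * rho)))
    exact <- ((1 + rho) / 2) / sqrt(1 + rho / 2)
    for (r_obs in c(cor(b$truth$raw_c, b$truth$raw_m),
                    cor(b$truth$raw_c, b$truth$raw_p))) {
      expect_lt(abs(r_obs - (1 + rho) / 2), 0.03)
      expect_lt(abs(r_obs - exact), 0.015)
    }
  }
})

test_that("phenotype model reduces to its analytic special cases", {
  b <- small_cohort()
  z <- b$truth
  # noiseless direct-only: Y is (re-standardized) z_c
  cfg <- sim_config(n_families = 300, delta = 1, eta_m = 0, eta_p = 0,
                    sigma_eps = 1e-9, beta_age = 0, beta_sex = 0)
  ph <- make_phenotypes(z$z_c, z$z_m, z$z_p, cfg, standardize = "overall", seed = 2)
  expect_lt(max(abs(ph$y - z$z_c / sd(z$z_c))), 1e-6)

  # null model: slope of Y on z_c indistinguishable from zero
  cfg0 <- sim_config(n_families = 300, delta = 0, eta_m = 0, eta_p = 0,
                     beta_age = 0, beta_sex = 0)
  ph0 <- make_phenotypes(z$z_c, z$z_m, z$z_p, cfg0, standardize = "overall", seed = 3)
  sl <- summary(lm(ph0$y ~ z$z_c))$coefficients["z$z_c", ]
  expect_lt(abs(sl["Estimate"]), 3 * sl["Std. Error"])
})

test_that("phenotype moments follow the generative covariance identity", {
  # Cov(Y, z_m) = eta_m + delta Cov(z_c, z_m) + eta_p Cov(z_p, z_m)
  b <- simulate_cohort(sim_config(n_variants = 120, n_families = 6000,
                                  mix = trio_only_mix(), rho_pp = 0,
                                  delta = 0.3, eta_m = 0.05, eta_p = 0.05,
                                  beta_age = 0, beta_sex = 0, seed = 77))
  z <- b$truth
  y <- b$phenotypes$y
  expected <- 0.05 + 0.3 * cor(z$z_c, z$z_m) + 0.05 * cor(z$z_p, z$z_m)
  se <- 1 / sqrt(nrow(z))
  expect_lt(abs(cov(y, z$z_m) - expected), 3 * se)
})

test_that("masking follows the family mix and reproduces the category bookkeeping", {
  b_trio <- simulate_cohort(sim_config(n_variants = 30, n_families = 50,
                                       mix = trio_only_mix(), seed = 4))
  expect_equal(b_trio$mask_counts$individuals, 0L)
  expect_equal(b_trio$mask_counts$units, 0L)

  b <- small_cohort()
  cnt <- table(b$truth$category)
  expect_equal(b$mask_counts$units,
               sum(cnt[c("duo_missing_father", "duo_missing_mother", "sibpair_no_parents")]))
  # masked parents have fully NA genotypes; everyone else is complete
  masked_ids <- b$mask$id[b$mask$masked]
  expect_true(all(is.na(b$panel$mat[match(masked_ids, b$panel$ids), ])))
  other <- setdiff(b$panel$ids, masked_ids)
  expect_false(anyNA(b$panel$mat[match(other, b$panel$ids), ]))

  # category re-assignment is seed-reproducible and validates feasibility
  m1 <- apply_missingness(b$truth_panel, b$pedigree, mix = family_mix(), seed = 9)
  m2 <- apply_missingness(b$truth_panel, b$pedigree, mix = family_mix(), seed = 9)
  expect_identical(m1$mask, m2$mask)
  greedy_mix <- family_mix(trio = 0, duo_missing_father = 0, duo_missing_mother = 0,
                           sibpair_no_parents = 1, sibpair_one_parent = 0)
  expect_error(apply_missingness(b$truth_panel, b$pedigree, mix = greedy_mix),
               "sibling families")
})

test_that("cohorts are Mendelian-consistent, conserve frequency and are reproducible", {
  b <- small_cohort()
  ped <- b$pedigree
  kids <- ped[ped$role %in% c("proband", "sib"), ]
  dos <- dosages(b$truth_panel)
  kid_rows <- match(kids$id, b$truth_panel$ids)
  mom_rows <- match(kids$mother_id, b$truth_panel$ids)
  dad_rows <- match(kids$father_id, b$truth_panel$ids)
  # no opposite homozygotes between child and either parent
  opp <- function(a, b_) sum((a == 0L & b_ == 2L) | (a == 2L & b_ == 0L))
  expect_equal(opp(dos[kid_rows, ], dos[mom_rows, ]), 0L)
  expect_equal(opp(dos[kid_rows, ], dos[dad_rows, ]), 0L)
  # maternal-slot allele is one of the mother's two alleles
  km <- b$truth_panel$mat[kid_rows, ]
  expect_true(all(km == b$truth_panel$mat[mom_rows, ] |
                    km == b$truth_panel$pat[mom_rows, ]))
  # offspring allele frequency tracks the founder frequency
  f_kid <- colMeans(dos[kid_rows, ]) / 2
  f_founder <- b$variants$alt_freq
  se <- sqrt(f_founder * (1 - f_founder) / (2 * length(kid_rows)))
  expect_true(all(abs(f_kid - f_founder) < 4 * se + 1e-9))

  b2 <- simulate_cohort(b$config)
  expect_identical(b$truth_panel$mat, b2$truth_panel$mat)
  expect_identical(b$phenotypes, b2$phenotypes)
  expect_identical(b$mask, b2$mask)
})
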
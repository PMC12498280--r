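test_that("duo imputation equals the exhaustive-enumeration posterior mean", {
  for (t in c(0L, 1L)) for (p in c(0.01, 0.1, 0.3, 0.5, 0.7, 0.95)) {
    expect_equal(impute_duo(t, p), enumerate_duo_posterior_mean(t, p),
                 tolerance = 1e-12)
  }
  expect_equal(impute_duo(1L, 0.3), 1.3)
  expect_equal(impute_duo(0L, 1e-9), 1e-9)
  expect_equal(enumerate_duo_posterior_mean(1, 0.5), 1.5)
  expect_error(impute_duo(2, 0.3), "transmitted")
})

test_that("sib emission model zeroes impossible configurations", {
  e <- sib_ibd_emissions(c(0L, 0L), c(2L, 0L), c(0.4, 0.4))
  expect_equal(unname(e[1, c("1", "2")]), c(0, 0))   # opposite homozygotes
  expect_gt(e[1, "0"], 0)
  expect_true(all(e[2, ] > 0))
  # each state's emission distribution sums to one over genotype pairs
  p <- 0.3
  gg <- expand.grid(g1 = 0:2, g2 = 0:2)
  em <- sib_ibd_emissions(gg$g1, gg$g2, rep(p, 9))
  expect_equal(unname(colSums(em)), c(1, 1, 1), tolerance = 1e-12)
})

test_that("forward-backward posteriors equal brute-force path enumeration", {
  p <- c(0.5, 0.5, 0.5)
  g1 <- c(0L, 1L, 2L)
  g2 <- c(0L, 1L, 1L)
  tr <- infer_sib_ibd(g1, g2, p, switch_prob = 0.1)
  brute <- enumerate_ibd_posterior(g1, g2, p, 0.1)
  expect_lt(max(abs(tr$posterior - brute)), 1e-10)

  set.seed(41)
  for (rep in 1:5) {
    p5 <- runif(5, 0.1, 0.9)
    g1 <- rbinom(5, 2, p5); g2 <- rbinom(5, 2, p5)
    s <- runif(1, 0.01, 0.3)
    tr <- infer_sib_ibd(g1, g2, p5, switch_prob = s)
    brute <- enumerate_ibd_posterior(g1, g2, p5, s)
    expect_lt(max(abs(tr$posterior - brute)), 1e-10)
  }
})

test_that("IBD decoding handles overwhelming and impossible evidence", {
  set.seed(13)
  p <- runif(200, 0.3, 0.7)
  g <- rbinom(200, 2, p)
  tr <- infer_sib_ibd(g, g, p, switch_prob = 1e-3)
  expect_true(all(tr$states == 2L))
  expect_equal(nrow(tr$segments), 1L)

  g_a <- rep(0L, 50); g_b <- rep(0L, 50); g_b[25] <- 2L   # opposite homozygote
  tr2 <- infer_sib_ibd(g_a, g_b, rep(0.4, 50), switch_prob = 0.01)
  expect_equal(tr2$posterior[25, "2"][[1]], 0)
  expect_equal(tr2$posterior[25, "1"][[1]], 0)
})

test_that("sib-pair parental-sum formulas match exhaustive enumeration", {
  # state 0: all four transmitted alleles observed
  s1 <- list(h1 = 1L, h2 = 0L); s2 <- list(h1 = 0L, h2 = 1L)
  ibd0 <- list(states = 0L, segments = data.frame(start = 1L, end = 1L, state = 0L))
  expect_equal(impute_from_sibpair(s1, s2, ibd0, 0.3)$expected_sum, 2)

  # state 2: only the untransmitted alleles are unknown
  s1 <- list(h1 = 0L, h2 = 0L); s2 <- list(h1 = 0L, h2 = 0L)
  ibd2 <- list(states = 2L, segments = data.frame(start = 1L, end = 1L, state = 2L))
  expect_equal(impute_from_sibpair(s1, s2, ibd2, 0.2)$expected_sum, 0.4)

  # state 1 grid against the enumeration oracle
  ibd1 <- list(states = 1L, segments = data.frame(start = 1L, end = 1L, state = 1L))
  cases <- list(list(g = c(2L, 1L), s = 1L, p = 0.5, sib1 = list(h1 = 1L, h2 = 1L),
                     sib2 = list(h1 = 1L, h2 = 0L)),
                list(g = c(1L, 2L), s = 1L, p = 0.3, sib1 = list(h1 = 1L, h2 = 0L),
                     sib2 = list(h1 = 1L, h2 = 1L)),
                list(g = c(1L, 0L), s = 0L, p = 0.2, sib1 = list(h1 = 0L, h2 = 1L),
                     sib2 = list(h1 = 0L, h2 = 0L)))
  for (cs in cases) {
    got <- impute_from_sibpair(cs$sib1, cs$sib2, ibd1, cs$p)$expected_sum
    oracle <- enumerate_sibpair_state1_sum(cs$g[1], cs$g[2], cs$s, cs$p)
    expect_equal(got, cs$g[1] + cs$g[2] - cs$s + cs$p, tolerance = 1e-12)
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # the quoted configuration: G1=2, G2=1, shared allele 1, p=0.5 -> 2.5
  expect_equal(enumerate_sibpair_state1_sum(2, 1, 1, 0.5), 2.5)
})

test_that("parent-of-origin assignment resolves phase or flags ambiguity", {
  # Mendelian forcing: parent dosage 0 excludes the 1-carrying haplotype
  r <- assign_parent_of_origin(child_h1 = c(0L, 0L, 1L), child_h2 = c(1L, 1L, 1L),
                               parent_dosage = c(0L, 0L, 2L))
  expect_equal(r$slot, 1L)
  expect_false(r$ambiguous)

  # parent and child heterozygous everywhere: uninformative tie
  r2 <- assign_parent_of_origin(rep(1L, 10), rep(0L, 10), rep(1L, 10))
  expect_true(r2$ambiguous)

  # simulated duos: the genotyped mother must map to the maternal slot
  b <- small_cohort()
  fams <- b$truth$family_id[b$truth$category == "duo_missing_father"][1:20]
  for (fm in fams) {
    ci <- match(paste0(fm, "_C1"), b$panel$ids)
    mi <- match(paste0(fm, "_M"), b$panel$ids)
    r <- assign_parent_of_origin(b$panel$mat[ci, ], b$panel$pat[ci, ],
                                 b$panel$mat[mi, ] + b$panel$pat[mi, ])
    if (!r$ambiguous) expect_equal(r$slot, 1L)
  }
})

test_that("duo imputation recovers the truth on average and exactly where determined", {
  b <- small_cohort()
  imp <- impute_missing_parents(b)
  ids <- rownames(imp$expected)
  truth_rows <- match(ids, b$truth_panel$ids)
  true_dos <- b$truth_panel$mat[truth_rows, ] + b$truth_panel$pat[truth_rows, ]
  # unbiasedness within Monte-Carlo error, per configuration
  for (cfg in unique(imp$info$configuration)) {
    sel <- imp$info$configuration == cfg
    diff <- mean(imp$expected[sel, ]) - mean(true_dos[sel, ])
    mc_se <- sd(imp$expected[sel, ] - true_dos[sel, ]) / sqrt(sum(sel) * ncol(true_dos))
    expect_lt(abs(diff), 4 * mc_se + 1e-8)
  }
  # duo expected dosages are t + p: within [p, 1 + p] bounds per variant
  duo <- imp$info$configuration == "duo" & !imp$info$ambiguous
  p <- b$variants$alt_freq
  expect_true(all(abs(sweep(imp$expected[duo, , drop = FALSE], 2, p) - 0.5) <= 0.5 + 1e-9))
})

test_that("sib-plus-parent imputation is exact on unshared segments", {
  cfg <- sim_config(n_variants = 200, n_families = 40, block_len = 50,
                    mix = family_mix(trio = 0, duo_missing_father = 0,
                                     duo_missing_mother = 0, sibpair_no_parents = 0,
                                     sibpair_one_parent = 1),
                    seed = 17)
  b <- simulate_cohort(cfg)
  imp <- impute_missing_parents(b)
  p <- b$variants$alt_freq
  fams <- imp$info$family_id[!imp$info$ambiguous]
  n_checked <- 0
  for (fm in fams) {
    s1 <- list(h1 = b$panel$mat[match(paste0(fm, "_C1"), b$panel$ids), ],
               h2 = b$panel$pat[match(paste0(fm, "_C1"), b$panel$ids), ])
    s2 <- list(h1 = b$panel$mat[match(paste0(fm, "_C2"), b$panel$ids), ],
               h2 = b$panel$pat[match(paste0(fm, "_C2"), b$panel$ids), ])
    mi <- match(paste0(fm, "_M"), b$panel$ids)
    r <- impute_sibpair_plus_parent(s1, s2, b$panel$mat[mi, ] + b$panel$pat[mi, ], p)
    if (r$degraded_to_duo) next
    ti <- match(paste0(fm, "_P"), b$truth_panel$ids)
    true_dos <- b$truth_panel$mat[ti, ] + b$truth_panel$pat[ti, ]
    unshared <- which(!r$shared)
    if (length(unshared)) {
      expect_equal(unname(r$expected[unshared]), unname(true_dos[unshared]))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 5)
})

test_that("masking experiment bookkeeping and accuracy behave as derived", {
  b <- simulate_cohort(sim_config(n_variants = 1200, n_families = 600,
                                  mix = trio_only_mix(), rho_pp = 0, seed = 23))
  expect_error(mask_and_score(b, fraction = 1.2), "fraction")
  expect_error(mask_and_score(b, fraction = -0.1), "fraction")
  zero <- mask_and_score(b, fraction = 0)
  expect_equal(zero$n_masked, 0L)
  expect_equal(zero$prs_correlation, 1)

  rep_ <- mask_and_score(b, fraction = 0.5, seed = 3)
  expect_equal(rep_$n_masked, 300L)
  # per-variant Pearson between t + p and t + u is analytically sqrt(1/2)
  expect_lt(abs(rep_$mean_pearson_by_variant - sqrt(0.5)), 0.02)
  # the allele-level Spearman measure sits below the Pearson value under
  # a MAF spectrum away from 0.5 (tied grades on discrete dosages)
  expect_lt(rep_$mean_spearman_by_variant, rep_$mean_pearson_by_variant)
  # deterministic under a fixed seed
  rep2 <- mask_and_score(b, fraction = 0.5, seed = 3)
  expect_identical(rep_$masked_ids, rep2$masked_ids)
  expect_equal(rep_$prs_correlation, rep2$prs_correlation)
})
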
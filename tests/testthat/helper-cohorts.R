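# shared fixtures, built once per test run

trio_only_mix <- function() {
  family_mix(trio = 1, duo_missing_father = 0, duo_missing_mother = 0,
             sibpair_no_parents = 0, sibpair_one_parent = 0)
}

# small mixed-configuration cohort reused across files
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_cohort(
      sim_config(n_variants = 120, n_families = 300, block_len = 12, seed = 11))
  }
  .fixture_env$small
}

# brute-force posterior for the sibling IBD HMM by path enumeration
enumerate_ibd_posterior <- function(g1, g2, p, switch_prob) {
  v <- length(g1)
  emit <- sib_ibd_emissions(as.integer(g1), as.integer(g2), p)
  trans <- matrix(c(1 - switch_prob, switch_prob, 0,
                    switch_prob, 1 - 2 * switch_prob, switch_prob,
                    0, switch_prob, 1 - switch_prob), 3, byrow = TRUE)
  init <- c(0.25, 0.5, 0.25)
  paths <- as.matrix(expand.grid(rep(list(1:3), v)))
  w <- apply(paths, 1, function(s) {
    pr <- init[s[1]] * emit[1, s[1]]
    if (v > 1) for (t in 2:v) pr <- pr * trans[s[t - 1], s[t]] * emit[t, s[t]]
    pr
  })
  post <- matrix(0, v, 3)
  for (t in 1:v) for (k in 1:3) post[t, k] <- sum(w[paths[, t] == k])
  post / rowSums(post)
}

# exhaustive posterior mean of a parent's dosage given the transmitted
# allele, enumerating HWE genotypes and transmission probabilities
enumerate_duo_posterior_mean <- function(t, p) {
  g <- 0:2
  prior <- dbinom(g, 2, p)
  lik <- if (t == 1) g / 2 else 1 - g / 2   # P(transmit allele t | G)
  post <- prior * lik
  sum(g * post) / sum(post)
}

# exhaustive E[mother+father dosage] for a sibling pair in IBD state 1
# given observed genotypes and the shared allele, enumerating all parental
# allele configurations and transmission choices
enumerate_sibpair_state1_sum <- function(g1, g2, s, p) {
  al <- c(0, 1)
  pr_al <- function(a) ifelse(a == 1, p, 1 - p)
  total_w <- 0; total_sum <- 0
  for (m1 in al) for (m2 in al) for (f1 in al) for (f2 in al) {
    w_conf <- pr_al(m1) * pr_al(m2) * pr_al(f1) * pr_al(f2)
    # shared parent: mother or father with equal prior; shared hap k;
    # other parent transmits independently to each sib
    for (shared_parent in c("m", "f")) for (k in 1:2) {
      sh <- if (shared_parent == "m") c(m1, m2)[k] else c(f1, f2)[k]
      for (j1 in 1:2) for (j2 in 1:2) {
        o1 <- if (shared_parent == "m") c(f1, f2)[j1] else c(m1, m2)[j1]
        o2 <- if (shared_parent == "m") c(f1, f2)[j2] else c(m1, m2)[j2]
        if (sh + o1 == g1 && sh + o2 == g2 && sh == s) {
          w <- w_conf * (1 / 2) * (1 / 2) * (1 / 4)
          total_w <- total_w + w
          total_sum <- total_sum + w * (m1 + m2 + f1 + f2)
        }
      }
    }
  }
  if (total_w == 0) return(NA_real_)
  total_sum / total_w
}

# direct simulation of relative pairs at the dosage level
simulate_relative_pairs <- function(n_pairs, n_variants, relationship, seed) {
  set.seed(seed)
  p <- runif(n_variants, 0.05, 0.5)
  draw_geno <- function(n) {
    matrix(rbinom(n * n_variants, 2, rep(p, each = n)), nrow = n)
  }
  draw_hap_from <- function(par_a, par_b) {
    # transmit one allele from a genotype pair given as two hap matrices
    coin <- matrix(rbinom(length(par_a), 1, 0.5), nrow = nrow(par_a))
    coin * par_a + (1 - coin) * par_b
  }
  hap <- function(n) matrix(rbinom(n * n_variants, 1, rep(p, each = n)), nrow = n)
  if (relationship == "unrelated") {
    return(list(a = draw_geno(n_pairs), b = draw_geno(n_pairs), p = p))
  }
  m1 <- hap(n_pairs); m2 <- hap(n_pairs)
  f1 <- hap(n_pairs); f2 <- hap(n_pairs)
  child <- function() draw_hap_from(m1, m2) + draw_hap_from(f1, f2)
  if (relationship == "parent-offspring") {
    return(list(a = m1 + m2, b = child(), p = p))
  }
  if (relationship == "full-sib") {
    return(list(a = child(), b = child(), p = p))
  }
  if (relationship == "first-cousin") {
    # sib parents from common grandparents, each mated to an unrelated spouse
    sib_a <- list(h1 = draw_hap_from(m1, m2), h2 = draw_hap_from(f1, f2))
    sib_b <- list(h1 = draw_hap_from(m1, m2), h2 = draw_hap_from(f1, f2))
    spouse <- function() list(h1 = hap(n_pairs), h2 = hap(n_pairs))
    sa <- spouse(); sb <- spouse()
    cousin_a <- draw_hap_from(sib_a$h1, sib_a$h2) + draw_hap_from(sa$h1, sa$h2)
    cousin_b <- draw_hap_from(sib_b$h1, sib_b$h2) + draw_hap_from(sb$h1, sb$h2)
    return(list(a = cousin_a, b = cousin_b, p = p))
  }
  stop("unknown relationship")
}

mean_pair_phi <- function(pairs) {
  vapply(seq_len(nrow(pairs$a)), function(i) {
    estimate_kinship(pairs$a[i, ], pairs$b[i, ])$phi
  }, numeric(1))
}
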
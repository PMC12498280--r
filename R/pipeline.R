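#' Pipeline run configuration
#'
#' Bundles the simulation configuration with the analysis toggles of a
#' reproducible end-to-end run. Every stochastic stage derives its seed
#' deterministically from the global seed and the stage name via
#' [derive_seed()].
#'
#' @param sim A [sim_config()]; its `seed` is overridden by the derived
#'   stage seed.
#' @param qc Apply the palindromic and MAF variant filters.
#' @param kinship Compute the proband kinship table (quadratic in
#'   probands; intended for demo-scale runs).
#' @param prune Restrict the regression to third-degree-unrelated probands.
#' @param n_pcs Number of proband PCs in the regression adjustment.
#' @param masking_fraction Fraction of complete trios to mask for the
#'   re-imputation quality experiment; `NULL` skips it.
#' @param seed Global integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(n_variants = 300, n_families = 600),
                       qc = TRUE, kinship = TRUE, prune = FALSE,
                       n_pcs = 10L, masking_fraction = 844 / 2736,
                       seed = 1L) {
  structure(list(sim = sim, qc = qc, kinship = kinship, prune = prune,
                 n_pcs = as.integer(n_pcs),
                 masking_fraction = masking_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the simulate -> QC -> impute -> score -> estimate pipeline
#'
#' Executes every stage on a fresh simulated cohort and persists the stage
#' artifacts under `out_dir`: phased genotypes (VCF-style text), pedigree
#' (FAM), phenotypes, weights and variant tables (TSV), the kinship table,
#' the PRS table, the fitted estimates (JSON + TSV forest table), the
#' optional masking-experiment report, and a `manifest.json` recording
#' stage seeds and artifact MD5 hashes. Re-running with the same
#' configuration reproduces all artifacts bit-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  art <- function(name) file.path(out_dir, name)
  add_stage <- function(stage, seed, files) {
    manifest$stages[[stage]] <<- list(
      seed = seed,
      files = as.list(tools::md5sum(file.path(out_dir, files))))
    write_manifest()
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[stage]] <<- list(error = conditionMessage(e))
      write_manifest()
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  # simulate ---------------------------------------------------------------
  sim_seed <- derive_seed(config$seed, "simulate")
  bundle <- run_stage("simulate", {
    cfg <- config$sim; cfg$seed <- sim_seed
    b <- simulate_cohort(cfg)
    write_phased_vcf(b$panel, art("genotypes.vcf"))
    write_fam(b$pedigree, art("pedigree.fam"))
    write_tsv(b$phenotypes, art("phenotypes.tsv"))
    write_tsv(b$weights, art("weights.tsv"))
    write_tsv(b$variants, art("variants.tsv"))
    write_tsv(b$truth, art("truth_prs.tsv"))
    b
  })
  add_stage("simulate", sim_seed,
            c("genotypes.vcf", "pedigree.fam", "phenotypes.tsv",
              "weights.tsv", "variants.tsv", "truth_prs.tsv"))

  # qc ----------------------------------------------------------------------
  if (config$qc) {
    run_stage("qc", {
      kept <- filter_maf(filter_palindromic(bundle$variants)$kept)$kept
      write_tsv(kept, art("variants_qc.tsv"))
      kept
    })
    add_stage("qc", NA, "variants_qc.tsv")
  }

  # kinship ------------------------------------------------------------------
  if (config$kinship) {
    run_stage("kinship", {
      prob <- paste0(bundle$truth$family_id, "_C1")
      kin <- kinship_pairs(dosages(bundle$panel)[match(prob, bundle$panel$ids), ,
                                                 drop = FALSE])
      write_tsv(kin, art("kinship.tsv"))
    })
    add_stage("kinship", NA, "kinship.tsv")
  }

  # impute + score + estimate ------------------------------------------------
  res <- run_stage("estimate", {
    r <- analyze_cohort(bundle, n_pcs = config$n_pcs, qc = config$qc,
                        prune = config$prune)
    if (!is.null(r$imputation$expected)) {
      imp_df <- data.frame(id = rownames(r$imputation$expected),
                           round(r$imputation$expected, 4),
                           check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv(imp_df, art("imputed_dosages.tsv"))
      write_tsv(r$imputation$info, art("imputation_info.tsv"))
    } else {
      message("imputation stage: zero imputed parents (all-trio mix); skipped")
      write_tsv(data.frame(), art("imputation_info.tsv"))
    }
    write_tsv(r$scores, art("prs.tsv"))
    fit <- r$fit
    est <- list(n = fit$n, delta = fit$delta, beta_m = fit$beta_m,
                beta_p = fit$beta_p, ige = fit$ige, se_delta = fit$se_delta,
                se_ige = fit$se_ige, ci_delta = fit$ci_delta,
                ci_ige = fit$ci_ige, ratio = fit$ratio,
                ratio_sq = fit$ratio_sq, delta_r2_prs = fit$delta_r2_prs,
                dge_r2 = fit$dge_r2, z_mp = fit$z_mp, p_mp = fit$p_mp)
    jsonlite::write_json(est, art("estimates.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    write_tsv(forest_table(cohort = fit), art("forest.tsv"))
    r
  })
  add_stage("estimate", NA,
            c("prs.tsv", "imputation_info.tsv", "estimates.json", "forest.tsv"))

  # masking experiment --------------------------------------------------------
  if (!is.null(config$masking_fraction) &&
      any(bundle$truth$category == "trio")) {
    mask_seed <- derive_seed(config$seed, "masking")
    run_stage("masking", {
      rep_ <- mask_and_score(bundle, fraction = config$masking_fraction,
                             seed = mask_seed)
      rep_$spearman_by_individual <- NULL
      rep_$masked_ids <- NULL
      jsonlite::write_json(rep_, art("masking_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    add_stage("masking", mask_seed, "masking_report.json")
  }

  report_run(out_dir)
  manifest$stages[["report"]] <- list(files = as.list(tools::md5sum(art("report.txt"))))
  write_manifest()
  invisible(manifest)
}

#' Human-readable summary of a pipeline run
#'
#' Collects the persisted artifacts of a run directory into `report.txt`:
#' family-mix counts, QC removals, imputation configuration counts,
#' masking-experiment accuracy and the estimates with confidence
#' intervals. An incomplete run produces a partial report flagged as such.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return The report lines, invisibly.
#' @export
report_run <- function(run_dir) {
  line <- function(...) sprintf(...)
  out <- c("nurturekit pipeline report", strrep("=", 26))
  partial <- FALSE
  grab <- function(name) {
    f <- file.path(run_dir, name)
    if (file.exists(f)) f else { partial <<- TRUE; NULL }
  }
  ped_f <- grab("pedigree.fam")
  if (!is.null(ped_f)) {
    ped <- read_fam(ped_f)
    out <- c(out, line("families: %d; individuals: %d",
                       length(unique(ped$family_id)), nrow(ped)))
  }
  imp_f <- grab("imputation_info.tsv")
  if (!is.null(imp_f)) {
    info <- tryCatch(read_tsv(imp_f), error = function(e) NULL)
    if (is.null(info) || nrow(info) == 0) {
      out <- c(out, "imputation: zero imputed parents")
    } else {
      tb <- table(info$configuration)
      out <- c(out, line("imputed parents: %d (%s)", nrow(info),
                         paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
    }
  }
  var_f <- grab("variants.tsv"); qc_f <- file.path(run_dir, "variants_qc.tsv")
  if (!is.null(var_f) && file.exists(qc_f)) {
    n_all <- nrow(read_tsv(var_f)); n_kept <- nrow(read_tsv(qc_f))
    out <- c(out, line("QC: %d of %d variants kept (%d removed)",
                       n_kept, n_all, n_all - n_kept))
  }
  mask_f <- file.path(run_dir, "masking_report.json")
  if (file.exists(mask_f)) {
    m <- jsonlite::read_json(mask_f)
    out <- c(out, line("masking experiment: %d of %d trios; mean allele Spearman %.3f; PRS correlation %.3f",
                       m$n_masked, m$n_trios, m$mean_spearman, m$prs_correlation))
  }
  est_f <- grab("estimates.json")
  if (!is.null(est_f)) {
    e <- jsonlite::read_json(est_f)
    out <- c(out,
             line("estimates (n = %d):", e$n),
             line("  DGE delta = %.3f (95%% CI %.3f - %.3f)", e$delta,
                  e$ci_delta[[1]], e$ci_delta[[2]]),
             line("  IGE = %.3f (95%% CI %.3f - %.3f)", e$ige,
                  e$ci_ige[[1]], e$ci_ige[[2]]),
             line("  ratio DGE/(IGE+DGE) = %.3f (squared %.3f)", e$ratio, e$ratio_sq),
             line("  PRS incremental R^2 = %.4f; DGE share = %.4f",
                  e$delta_r2_prs, e$dge_r2),
             line("  maternal-paternal z = %.2f (p = %.3g)", e$z_mp, e$p_mp))
  }
  if (partial) out <- c(out, "", "WARNING: incomplete run; partial report")
  writeLines(out, file.path(run_dir, "report.txt"))
  invisible(out)
}
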
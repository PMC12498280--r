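#' Write a phased haplotype panel as VCF-style text
#'
#' Minimal VCF (4.2 header, `GT` format only): phased genotypes are written
#' `a|b` with the maternal-origin allele first, masked individuals as
#' `./.`, and the in-sample alternate-allele frequency in `INFO/AF`.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  v <- panel$variants
  gt <- matrix(paste0(panel$mat, "|", panel$pat), nrow = nrow(panel$mat))
  gt[is.na(panel$mat)] <- "./."
  lines <- c("##fileformat=VCFv4.2",
             "##source=nurturekit",
             "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype, maternal allele first\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
                     panel$ids), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                sprintf("AF=%.6g", v$alt_freq), "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a phased VCF-style file into a haplotype panel
#'
#' Only `GT` data are consumed. Non-missing genotypes must be phased
#' (`|` separator); an unphased `/` separator is a hard error naming the
#' offending variant and sample. `./.` marks a fully masked individual.
#'
#' @param path VCF file path.
#' @return A [haplotype_panel()]; `alt_freq` is taken from `INFO/AF` when
#'   present, otherwise recomputed from the non-missing dosages.
#' @export
read_phased_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stopf("%s: missing #CHROM header line", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  if (!length(body)) stopf("%s: no variant records", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  fixed <- t(vapply(fields, function(f) f[1:9], character(9)))
  af <- suppressWarnings(as.numeric(sub("^.*AF=([^;]+).*$", "\\1", fixed[, 8])))
  gt <- t(vapply(fields, function(f) f[-(1:9)], character(length(ids))))
  if (length(ids) == 1L) gt <- matrix(gt, ncol = 1L)
  bad <- grepl("/", gt, fixed = TRUE) & gt != "./."
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stopf("%s: unphased genotype '%s' at variant %s, sample %s",
          path, gt[w[1], w[2]], fixed[w[1], 3], ids[w[2]])
  }
  ok <- gt == "./." | grepl("^[01]\\|[01]$", gt)
  if (!all(ok)) {
    w <- which(!ok, arr.ind = TRUE)[1, ]
    stopf("%s: malformed genotype '%s' at variant %s, sample %s",
          path, gt[w[1], w[2]], fixed[w[1], 3], ids[w[2]])
  }
  pick <- function(k) {
    a <- substr(gt, k, k)
    a[gt == "./."] <- NA
    t(array(as.integer(a), dim = dim(gt)))
  }
  mat <- pick(1L); pat <- pick(3L)
  variants <- data.frame(variant_id = fixed[, 3], chrom = fixed[, 1],
                         pos = as.integer(fixed[, 2]), ref = fixed[, 4],
                         alt = fixed[, 5], alt_freq = af, stringsAsFactors = FALSE)
  if (anyNA(variants$alt_freq)) {
    d <- mat + pat
    variants$alt_freq <- ifelse(is.na(variants$alt_freq),
                                colMeans(d, na.rm = TRUE) / 2, variants$alt_freq)
  }
  haplotype_panel(mat, pat, variants, ids)
}

#' Write / read a FAM-style pedigree table
#'
#' Whitespace-delimited, no header: `family_id id father_id mother_id sex
#' phenotype` with `0` for unknown parents and `-9` as the phenotype
#' placeholder.
#'
#' @param pedigree Pedigree `data.frame` (columns `family_id`, `id`,
#'   `father_id`, `mother_id`, `sex`; a `phenotype` column is optional).
#' @param path File path.
#' @return `path` (writer, invisibly) or the pedigree `data.frame` (reader).
#' @export
write_fam <- function(pedigree, path) {
  pheno <- pedigree$phenotype %||% rep(-9, nrow(pedigree))
  out <- data.frame(pedigree$family_id, pedigree$id, pedigree$father_id,
                    pedigree$mother_id, pedigree$sex, pheno)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_fam
#' @export
read_fam <- function(path) {
  out <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "id", "father_id",
                                         "mother_id", "sex", "phenotype"))
  out$sex <- as.integer(out$sex)
  out
}

#' Write / read a tab-delimited table with header
#'
#' Used for weight tables (`variant_id`, `effect_allele`, `weight`),
#' phenotype/covariate tables, kinship tables and PRS tables.
#'
#' @param x A `data.frame`.
#' @param path File path.
#' @return `path` (writer, invisibly) or a `data.frame` (reader).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Remove palindromic variants with ambiguous frequency
#'
#' A variant is palindromic when its allele pair is \{A,T\} or \{C,G\}
#' (strand cannot be resolved from the alleles alone); it is removed when,
#' in addition, its alternate-allele frequency lies inside the ambiguity
#' band `[freq_lo, freq_hi]`.
#'
#' @param variants Variant table with `ref`, `alt`, `alt_freq`.
#' @param freq_lo,freq_hi Ambiguity band bounds (inclusive).
#' @return List with `kept` and `removed` variant tables.
#' @export
#' @examples
#' vt <- data.frame(variant_id = c("a", "b", "c"), ref = c("A", "A", "A"),
#'                  alt = c("T", "T", "G"), alt_freq = c(0.5, 0.1, 0.5))
#' filter_palindromic(vt)$removed$variant_id
filter_palindromic <- function(variants, freq_lo = 0.40, freq_hi = 0.60) {
  pair <- paste(pmin(variants$ref, variants$alt), pmax(variants$ref, variants$alt))
  palindromic <- pair %in% c("A T", "C G")
  remove <- palindromic & variants$alt_freq >= freq_lo & variants$alt_freq <= freq_hi
  message(sprintf("palindromic filter: removed %d of %d variants", sum(remove), nrow(variants)))
  list(kept = variants[!remove, , drop = FALSE], removed = variants[remove, , drop = FALSE])
}

#' Remove variants associated with genotyping batch
#'
#' Per variant, an allelic 2x2 chi-square (alleles x batch, no continuity
#' correction) tests association between allele counts and the binary
#' batch label; variants with `p < alpha` are removed. Monomorphic
#' variants are assigned `p = 1`.
#'
#' @param dosage_matrix Individuals x variants dosage matrix.
#' @param batch Binary (0/1) batch label per individual; both batches must
#'   be non-empty.
#' @param variants Variant table aligned with the dosage columns.
#' @param alpha Removal threshold on the chi-square p-value.
#' @return List with `kept`, `removed` and the per-variant `p` values.
#' @export
filter_batch_associated <- function(dosage_matrix, batch, variants, alpha = 1e-5) {
  batch <- as.integer(batch)
  if (!all(batch %in% c(0L, 1L))) stopf("batch labels must be 0/1")
  n1 <- sum(batch == 1L); n0 <- sum(batch == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both batches must contain at least one sample")
  alt1 <- colSums(dosage_matrix[batch == 1L, , drop = FALSE], na.rm = TRUE)
  alt0 <- colSums(dosage_matrix[batch == 0L, , drop = FALSE], na.rm = TRUE)
  m1 <- 2 * colSums(!is.na(dosage_matrix[batch == 1L, , drop = FALSE]))
  m0 <- 2 * colSums(!is.na(dosage_matrix[batch == 0L, , drop = FALSE]))
  aa <- alt1; bb <- m1 - alt1; cc <- alt0; dd <- m0 - alt0
  n <- aa + bb + cc + dd
  denom <- (aa + bb) * (cc + dd) * (aa + cc) * (bb + dd)
  chi2 <- ifelse(denom > 0, n * (aa * dd - bb * cc)^2 / denom, 0)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  remove <- p < alpha
  message(sprintf("batch filter: removed %d of %d variants at alpha = %g",
                  sum(remove), nrow(variants), alpha))
  list(kept = variants[!remove, , drop = FALSE],
       removed = variants[remove, , drop = FALSE], p = p)
}

#' Minor-allele-frequency filter
#'
#' Keeps variants whose minor-allele frequency `min(p, 1 - p)` is at least
#' `maf_min` (inclusive bound).
#'
#' @param variants Variant table with `alt_freq`.
#' @param maf_min Minimum minor-allele frequency.
#' @return List with `kept` and `removed` variant tables.
#' @export
filter_maf <- function(variants, maf_min = 0.01) {
  maf <- pmin(variants$alt_freq, 1 - variants$alt_freq)
  keep <- maf >= maf_min
  list(kept = variants[keep, , drop = FALSE], removed = variants[!keep, , drop = FALSE])
}

#' Hardy-Weinberg and call-rate filters
#'
#' Optional array-QC style filters, off by default in simulated pipelines
#' (simulated founders satisfy HWE by construction). `filter_hwe` removes
#' variants whose genotype counts deviate from Hardy-Weinberg proportions
#' (1-df chi-square) at `p < alpha`; `filter_callrate` removes variants
#' with per-variant call rate below `min_call`.
#'
#' @param dosage_matrix Individuals x variants dosage matrix.
#' @param variants Variant table aligned with the columns.
#' @param alpha HWE exclusion threshold.
#' @param min_call Minimum call rate.
#' @return List with `kept` and `removed` variant tables.
#' @export
filter_hwe <- function(dosage_matrix, variants, alpha = 1e-7) {
  n_aa <- colSums(dosage_matrix == 0L, na.rm = TRUE)
  n_ab <- colSums(dosage_matrix == 1L, na.rm = TRUE)
  n_bb <- colSums(dosage_matrix == 2L, na.rm = TRUE)
  n <- n_aa + n_ab + n_bb
  p <- (2 * n_bb + n_ab) / (2 * n)
  e_aa <- n * (1 - p)^2; e_ab <- 2 * n * p * (1 - p); e_bb <- n * p^2
  chi2 <- ifelse(p > 0 & p < 1,
                 (n_aa - e_aa)^2 / e_aa + (n_ab - e_ab)^2 / e_ab + (n_bb - e_bb)^2 / e_bb,
                 0)
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  keep <- pval >= alpha
  list(kept = variants[keep, , drop = FALSE], removed = variants[!keep, , drop = FALSE])
}

#' @rdname filter_hwe
#' @export
filter_callrate <- function(dosage_matrix, variants, min_call = 0.975) {
  call <- colMeans(!is.na(dosage_matrix))
  keep <- call >= min_call
  list(kept = variants[keep, , drop = FALSE], removed = variants[!keep, , drop = FALSE])
}
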
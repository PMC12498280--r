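#' Phased haplotype panel
#'
#' A container for phased diploid genotypes: two integer allele matrices
#' (individuals x variants) with the fixed slot convention that slot `mat`
#' holds the maternally inherited allele and slot `pat` the paternally
#' inherited allele wherever parent of origin is known (founders receive an
#' arbitrary but fixed slot order). Masked (ungenotyped) individuals carry
#' `NA` in both slots.
#'
#' @param mat,pat Integer 0/1 matrices of identical dimension, rows =
#'   individuals, columns = variants.
#' @param variants A variant table (`data.frame` with columns `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `alt_freq`).
#' @param ids Character individual identifiers, one per row.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(mat, pat, variants, ids) {
  stopifnot(is.matrix(mat), is.matrix(pat), all(dim(mat) == dim(pat)),
            nrow(mat) == length(ids), ncol(mat) == nrow(variants))
  ok <- function(x) all(x %in% c(0L, 1L) | is.na(x))
  if (!ok(mat) || !ok(pat)) stopf("haplotype alleles must be 0, 1 or NA")
  rownames(mat) <- rownames(pat) <- ids
  structure(list(mat = mat, pat = pat, variants = variants, ids = ids),
            class = "haplotype_panel")
}

#' Allele dosages of a panel
#'
#' @param panel A [haplotype_panel()].
#' @return Integer matrix of alternate-allele dosages in 0..2 (`NA` where
#'   masked), individuals x variants.
#' @export
dosages <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  d <- panel$mat + panel$pat
  colnames(d) <- panel$variants$variant_id
  d
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d individuals x %d variants (%d masked)\n",
              nrow(x$mat), ncol(x$mat), sum(is.na(x$mat[, 1L]))))
  invisible(x)
}

# row-subset of a panel, keeping the variant table
panel_subset <- function(panel, ids) {
  idx <- match(ids, panel$ids)
  if (anyNA(idx)) stopf("unknown individual id(s): %s", paste(ids[is.na(idx)], collapse = ", "))
  haplotype_panel(panel$mat[idx, , drop = FALSE], panel$pat[idx, , drop = FALSE],
                  panel$variants, panel$ids[idx])
}

# stack panels over the same variant table
panel_rbind <- function(...) {
  ps <- list(...)
  haplotype_panel(do.call(rbind, lapply(ps, `[[`, "mat")),
                  do.call(rbind, lapply(ps, `[[`, "pat")),
                  ps[[1L]]$variants,
                  unlist(lapply(ps, `[[`, "ids")))
}
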
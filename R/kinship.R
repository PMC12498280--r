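#' KING-robust kinship coefficient for one pair
#'
#' `phi = (N_het,het - 2 N_opp) / (N_het(i) + N_het(j))`, where `N_het,het`
#' counts variants at which both individuals are heterozygous, `N_opp`
#' counts opposite homozygotes, and the denominator sums both individuals'
#' heterozygote counts over the non-missing overlap (the symmetric variant
#' of the estimator). Expectation ~0.5 for duplicates/MZ twins, ~0.25 for
#' first-degree relatives, ~0 for unrelated pairs.
#'
#' @param dos_i,dos_j Integer dosage vectors (0/1/2, `NA` allowed).
#' @param min_overlap Minimum non-missing overlapping variants; below it
#'   the estimate is returned with `low_confidence = TRUE`.
#' @return List with `phi`, `ibs0_rate` (opposite-homozygote rate over the
#'   overlap), `n_informative` and `low_confidence`.
#' @export
#' @examples
#' estimate_kinship(c(0, 1, 1, 2), c(0, 1, 1, 2))$phi  # duplicate: 0.5
estimate_kinship <- function(dos_i, dos_j, min_overlap = 100L) {
  keep <- !is.na(dos_i) & !is.na(dos_j)
  x <- dos_i[keep]; y <- dos_j[keep]
  n <- length(x)
  het_i <- sum(x == 1L); het_j <- sum(y == 1L)
  het_both <- sum(x == 1L & y == 1L)
  opp <- sum((x == 0L & y == 2L) | (x == 2L & y == 0L))
  denom <- het_i + het_j
  phi <- if (denom > 0) (het_both - 2 * opp) / denom else NA_real_
  list(phi = phi, ibs0_rate = if (n > 0) opp / n else NA_real_,
       n_informative = n, low_confidence = n < min_overlap)
}

#' All-pairs KING-robust kinship for a dosage matrix
#'
#' Vectorized counterpart of [estimate_kinship()] for complete (no-`NA`)
#' dosage matrices, returning a tidy pair table.
#'
#' @param dosage_matrix Individuals x variants 0/1/2 matrix without missing
#'   values (rows named by individual id).
#' @param classify If `TRUE`, append the relationship class from
#'   [classify_pair()].
#' @return `data.frame(id_i, id_j, n_informative, phi, ibs0_rate[, class])`
#'   for all unordered pairs.
#' @export
kinship_pairs <- function(dosage_matrix, classify = TRUE) {
  if (anyNA(dosage_matrix)) stopf("kinship_pairs requires a complete dosage matrix")
  X <- dosage_matrix
  H <- (X == 1L) * 1; A <- (X == 0L) * 1; B <- (X == 2L) * 1
  het_both <- tcrossprod(H)
  opp <- tcrossprod(A, B); opp <- opp + t(opp)
  het <- rowSums(H)
  denom <- outer(het, het, `+`)
  phi <- (het_both - 2 * opp) / denom
  n <- ncol(X)
  ids <- rownames(X) %||% sprintf("I%06d", seq_len(nrow(X)))
  pr <- which(upper.tri(phi), arr.ind = TRUE)
  out <- data.frame(id_i = ids[pr[, 1]], id_j = ids[pr[, 2]],
                    n_informative = n, phi = phi[pr],
                    ibs0_rate = opp[pr] / n, stringsAsFactors = FALSE)
  if (classify) out$class <- classify_pair(out$phi, out$ibs0_rate)
  out
}

#' Classify a pair of individuals by kinship coefficient
#'
#' Fixed KING-convention thresholds: `phi >= 0.354` duplicate/MZ;
#' `[0.177, 0.354)` first degree, split into parent-offspring versus full
#' siblings by the opposite-homozygote rate (~0 for parent-offspring, which
#' cannot show opposite homozygotes); `[0.0884, 0.177)` second degree;
#' `[0.0442, 0.0884)` third degree; below, unrelated. The 0.177
#' first-degree bound is inclusive.
#'
#' @param phi Kinship coefficient(s).
#' @param ibs0_rate Opposite-homozygote rate(s); `NA` leaves first-degree
#'   pairs unsplit.
#' @param ibs0_max Parent-offspring threshold on the opposite-homozygote
#'   rate.
#' @return Character vector of classes.
#' @export
#' @examples
#' classify_pair(c(0.5, 0.25, 0.25, 0.1, 0.06, 0.01), c(0, 0, 0.01, NA, NA, NA))
classify_pair <- function(phi, ibs0_rate = NA_real_, ibs0_max = 0.001) {
  ibs0_rate <- rep_len(ibs0_rate, length(phi))
  cls <- rep("unrelated", length(phi))
  cls[phi >= 0.0442] <- "third-degree"
  cls[phi >= 0.0884] <- "second-degree"
  first <- phi >= 0.177 & phi < 0.354
  cls[first] <- ifelse(is.na(ibs0_rate[first]), "first-degree",
                       ifelse(ibs0_rate[first] <= ibs0_max,
                              "parent-offspring", "full-sib"))
  cls[phi >= 0.354] <- "duplicate/MZ"
  cls
}

#' Greedy pruning to an unrelated set of probands
#'
#' Builds the relatedness graph over probands (edges where `phi` meets the
#' bound for the requested degree) and iteratively removes the proband with
#' the most remaining edges, ties broken by id sort order, until no edges
#' remain. Greedy removal is deterministic and close to, but not always
#' exactly, the minimum number of removals.
#'
#' @param ids Character proband ids.
#' @param kinship Pair table with `id_i`, `id_j`, `phi` (e.g. from
#'   [kinship_pairs()]).
#' @param degree Relatedness degree to prune to: pairs related at this
#'   degree *or closer* are broken up. `3` (default) uses the conventional
#'   bound `phi >= 2^(-9/2) = 0.0442`.
#' @return Character vector of retained ids.
#' @export
prune_independent <- function(ids, kinship, degree = 3L) {
  bound <- c(`1` = 0.177, `2` = 0.0884, `3` = 0.0442)[as.character(degree)]
  if (is.na(bound)) stopf("degree must be 1, 2 or 3")
  edges <- kinship[kinship$phi >= bound &
                     kinship$id_i %in% ids & kinship$id_j %in% ids, c("id_i", "id_j")]
  keep <- sort(ids)
  while (nrow(edges) > 0) {
    deg <- table(c(edges$id_i, edges$id_j))
    worst <- names(deg)[deg == max(deg)]
    drop <- sort(worst)[1]                 # tie-break: first in id order
    keep <- setdiff(keep, drop)
    edges <- edges[edges$id_i != drop & edges$id_j != drop, , drop = FALSE]
  }
  keep[order(match(keep, ids))]
}

#' Euclidean-distance ancestry gate on two principal components
#'
#' Computes the centroid of the reference samples on the first two
#' principal components and the maximum reference distance to that
#' centroid; study samples within that radius (inclusive) are labeled
#' `in`, all others `out`.
#'
#' @param sample_pcs n x 2 matrix of study-sample PC coordinates.
#' @param reference_pcs m x 2 matrix of reference-panel PC coordinates
#'   (same components).
#' @return List with logical `in_gate`, the `center` and the `radius`.
#' @export
ancestry_gate <- function(sample_pcs, reference_pcs) {
  reference_pcs <- as.matrix(reference_pcs)
  sample_pcs <- as.matrix(sample_pcs)
  if (nrow(reference_pcs) == 0) stopf("empty ancestry reference set")
  stopifnot(ncol(sample_pcs) == 2, ncol(reference_pcs) == 2)
  center <- colMeans(reference_pcs)
  radius <- max(sqrt(colSums((t(reference_pcs) - center)^2)))
  d <- sqrt(colSums((t(sample_pcs) - center)^2))
  list(in_gate = d <= radius, center = center, radius = radius, distance = d)
}

#' Principal components of a dosage matrix
#'
#' Centers each variant at twice its allele frequency and scales by the
#' binomial SD `sqrt(2 p (1-p))` before the eigendecomposition;
#' monomorphic variants are dropped.
#'
#' @param dosage_matrix Individuals x variants dosage matrix (no `NA`).
#' @param n_pcs Number of components to return.
#' @return n x `n_pcs` matrix of PC scores.
#' @export
pca_dosages <- function(dosage_matrix, n_pcs = 10L) {
  p <- colMeans(dosage_matrix) / 2
  keep <- p > 0 & p < 1
  X <- dosage_matrix[, keep, drop = FALSE]
  p <- p[keep]
  S <- sweep(sweep(X, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), `/`)
  n_pcs <- min(n_pcs, ncol(S), nrow(S) - 1L)
  eig <- eigen(crossprod(S), symmetric = TRUE)
  scores <- S %*% eig$vectors[, seq_len(n_pcs), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  scores
}

#' Greedy linkage-disequilibrium thinning
#'
#' Walks variants in position order and keeps a variant only if its squared
#' correlation with every already-kept variant within the window stays at
#' or below `r2_max`.
#'
#' @param dosage_matrix Individuals x variants dosage matrix.
#' @param pos Base-pair positions per variant.
#' @param r2_max Squared-correlation ceiling.
#' @param window_bp Window width in base pairs.
#' @return Integer indices of retained variants.
#' @export
ld_thin <- function(dosage_matrix, pos, r2_max = 0.2, window_bp = 50000) {
  ord <- order(pos)
  kept <- integer(0)
  for (v in ord) {
    near <- kept[pos[kept] >= pos[v] - window_bp]
    ok <- TRUE
    for (k in near) {
      r <- suppressWarnings(stats::cor(dosage_matrix[, v], dosage_matrix[, k]))
      if (is.finite(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, v)
  }
  sort(kept)
}
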
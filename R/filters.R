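#' Per-pair missingness filter
#'
#' Keeps a site if and only if the fraction of genotyped individuals is at
#' least `threshold` in *each* of the two populations. A diploid call is
#' either genotyped or not (half-calls were already collapsed to missing at
#' read time), and exactly the threshold fraction passes: with the default
#' 0.75, a site where 3 of 4 individuals are genotyped is kept.
#'
#' The filter is symmetric in the two populations and idempotent.
#'
#' @param G a [genotype_matrix()].
#' @param popA,popB disjoint, non-empty sample-id vectors.
#' @param threshold minimum genotyped fraction per population (default 0.75).
#' @return logical site mask (TRUE = keep).
#' @export
filter_pair_missingness <- function(G, popA, popB, threshold = 0.75) {
  ia <- sample_index(G, popA, "popA sample")
  ib <- sample_index(G, popB, "popB sample")
  if (length(intersect(ia, ib))) stop("popA and popB overlap")
  fa <- rowMeans(!is.na(G$a1[, ia, drop = FALSE]))
  fb <- rowMeans(!is.na(G$a1[, ib, drop = FALSE]))
  fa >= threshold & fb >= threshold
}

#' Invariant-site mask
#'
#' Keeps sites where at least two distinct alleles are observed among the
#' non-missing calls of the listed samples. A difference fixed between two
#' populations is variant only when both populations are in the sample list.
#'
#' @param G a [genotype_matrix()].
#' @param samples non-empty sample-id vector.
#' @return logical site mask (TRUE = keep, i.e. site is variant).
#' @export
remove_invariant_sites <- function(G, samples) {
  idx <- sample_index(G, samples)
  a1 <- G$a1[, idx, drop = FALSE]
  a2 <- G$a2[, idx, drop = FALSE]
  lo <- pmin(suppressWarnings(apply(a1, 1L, min, na.rm = TRUE)),
             suppressWarnings(apply(a2, 1L, min, na.rm = TRUE)))
  hi <- pmax(suppressWarnings(apply(a1, 1L, max, na.rm = TRUE)),
             suppressWarnings(apply(a2, 1L, max, na.rm = TRUE)))
  is.finite(lo) & is.finite(hi) & hi > lo
}
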
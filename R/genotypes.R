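#' Diploid genotype matrix anchored to a contig
#'
#' The central container of the package: a sites-by-samples table of diploid
#' genotype calls on one contig. Calls are stored as two integer matrices of
#' 1-based allele indices into the per-site allele list (reference allele
#' first); a missing genotype is `NA` in both matrices. Coordinates are
#' 1-based and inclusive throughout the package, matching the VCF convention.
#'
#' @param contig single contig name.
#' @param positions integer vector of 1-based site coordinates, strictly
#'   increasing.
#' @param alleles list (one element per site) of character vectors of allele
#'   labels, reference first. Every site needs at least one allele.
#' @param a1,a2 integer matrices (`length(positions)` rows, one column per
#'   sample) of allele indices; `NA` in both marks a missing call. A
#'   half-call is not representable: callers must missing-out the whole
#'   genotype (see [read_genotypes()]).
#' @param samples character vector of sample identifiers (column names).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(contig, positions, alleles, a1, a2, samples) {
  stopifnot(is.character(contig), length(contig) == 1L)
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing on contig '", contig, "'")
  n_sites <- length(positions)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("a1 and a2 must have identical dimensions")
  if (nrow(a1) != n_sites)
    stop("call matrices must have one row per site")
  if (length(alleles) != n_sites)
    stop("alleles must have one entry per site")
  if (ncol(a1) != length(samples))
    stop("call matrices must have one column per sample")
  if (anyDuplicated(samples))
    stop("duplicated sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  # half-calls are not representable: NA must pair with NA
  if (any(is.na(a1) != is.na(a2)))
    stop("half-missing calls are not allowed; set both allele slots to NA")
  n_all <- lengths(alleles)
  if (any(n_all < 1L)) stop("every site needs at least one allele")
  mx1 <- suppressWarnings(apply(a1, 1L, max, na.rm = TRUE))
  mx2 <- suppressWarnings(apply(a2, 1L, max, na.rm = TRUE))
  mx <- pmax(mx1, mx2)
  bad <- which(is.finite(mx) & mx > n_all)
  if (length(bad))
    stop("call at site ", positions[bad[1L]],
         " indexes an allele beyond the allele list")
  colnames(a1) <- colnames(a2) <- samples
  structure(
    list(contig = contig, positions = positions, alleles = alleles,
         a1 = a1, a2 = a2, samples = samples),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples on '%s'\n",
              n_sites(x), length(x$samples), x$contig))
  if (n_sites(x)) {
    miss <- mean(is.na(x$a1))
    cat(sprintf("  positions %d..%d, %.1f%% missing calls, max %d alleles/site\n",
                min(x$positions), max(x$positions), 100 * miss,
                max(lengths(x$alleles))))
  }
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param G a `genotype_matrix`.
#' @return integer site count.
#' @export
n_sites <- function(G) length(G$positions)

#' Subset a genotype matrix to a genomic interval
#'
#' Keeps all and only the sites whose position lies inside `[start, end]`
#' (1-based, both ends inclusive). Original coordinates are retained; an
#' empty result is a valid empty matrix, not an error.
#'
#' @param G a `genotype_matrix`.
#' @param start,end interval bounds, 1-based inclusive.
#' @return a `genotype_matrix` with the selected sites.
#' @export
subset_region <- function(G, start, end) {
  stopifnot(inherits(G, "genotype_matrix"), start <= end)
  keep <- G$positions >= start & G$positions <= end
  subset_sites(G, keep)
}

#' Subset a genotype matrix by a logical site mask
#'
#' Masks compose and are idempotent: applying the same mask twice (suitably
#' re-indexed) equals applying it once.
#'
#' @param G a `genotype_matrix`.
#' @param keep logical vector, one element per site.
#' @return a `genotype_matrix`.
#' @export
subset_sites <- function(G, keep) {
  stopifnot(inherits(G, "genotype_matrix"), length(keep) == n_sites(G))
  keep <- which(keep)
  genotype_matrix(G$contig, G$positions[keep], G$alleles[keep],
                  G$a1[keep, , drop = FALSE], G$a2[keep, , drop = FALSE],
                  G$samples)
}

#' Subset a genotype matrix to a set of samples
#' @param G a `genotype_matrix`.
#' @param samples sample ids to keep (order respected).
#' @return a `genotype_matrix`.
#' @export
subset_samples <- function(G, samples) {
  idx <- match(samples, G$samples)
  if (anyNA(idx))
    stop("samples absent from matrix: ",
         paste(samples[is.na(idx)], collapse = ", "))
  genotype_matrix(G$contig, G$positions, G$alleles,
                  G$a1[, idx, drop = FALSE], G$a2[, idx, drop = FALSE],
                  samples)
}

# column indices for a sample id vector, with a hard error naming absentees
sample_index <- function(G, samples, what = "sample") {
  if (length(samples) == 0L) stop("empty ", what, " list")
  idx <- match(samples, G$samples)
  if (anyNA(idx))
    stop(what, "(s) absent from genotype matrix: ",
         paste(samples[is.na(idx)], collapse = ", "))
  idx
}
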
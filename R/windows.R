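#' Sliding windows along a contig
#'
#' Windows are anchored at position 1, advance by `step` and are never
#' truncated: only full-size windows are emitted, so a contig shorter than
#' `size` yields an empty set and the count for longer contigs is
#' `floor((L - size) / step) + 1`. Coordinates are 1-based inclusive.
#'
#' @param contig_length contig length L in bp.
#' @param size window size in bp (default 15000).
#' @param step step in bp (default 5000); must satisfy `size >= step > 0`.
#' @param contig optional contig name carried on the result.
#' @return data.frame with columns `contig`, `start`, `end`, `mid`.
#' @export
make_windows <- function(contig_length, size = 15000L, step = 5000L,
                         contig = NA_character_) {
  stopifnot(size >= step, step > 0)
  contig_length <- as.numeric(contig_length)
  if (contig_length < size)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), mid = numeric()))
  n <- floor((contig_length - size) / step) + 1
  start <- as.integer(1 + (seq_len(n) - 1) * step)
  end <- as.integer(start + size - 1L)
  data.frame(contig = contig, start = start, end = end,
             mid = (start + end) / 2)
}

#' Windowed divergence estimates
#'
#' For each window, theta-hat by the ratio-of-sums rule and mean d_xy over
#' the defined positions falling inside it. Coverage is the fraction of the
#' window's genomic positions that carry an estimate (defined sites /
#' window size in bp); windows below `min_coverage` are still emitted but
#' carry `NA` estimates. With the default 0.20, a 15-kb window needs at
#' least 3,000 positions with estimates -- exactly 3,000 passes.
#'
#' The bp denominator presumes resequencing-dense input where nearly every
#' genomic position is genotyped (invariant positions included). For
#' SNP-only inputs -- such as the synthetic generator's output -- set
#' `denominator = "records"` to measure coverage against the positions
#' present in the input instead of the window's physical size.
#'
#' @param components `site_components` from [site_components()], or a list
#'   of them from the member pairs of a group (components are summed across
#'   members within each window, the group combining rule at window scale).
#' @param dxy matching [site_dxy()] frame or list.
#' @param windows data.frame from [make_windows()].
#' @param min_coverage minimum coverage fraction (default 0.20).
#' @param denominator `"bp"` (window size, the default) or `"records"`
#'   (distinct input positions in the window) as the coverage denominator.
#' @return `windows` with added columns `theta`, `dxy_mean`, `coverage`,
#'   `n_positions`, `sum_num`, `sum_den`.
#' @export
window_estimates <- function(components, dxy, windows, min_coverage = 0.20,
                             denominator = c("bp", "records")) {
  denominator <- match.arg(denominator)
  if (inherits(components, "site_components")) components <- list(components)
  if (is.data.frame(dxy)) dxy <- list(dxy)
  pos <- unlist(lapply(components, `[[`, "position"))
  a <- unlist(lapply(components, `[[`, "a"))
  den <- a + unlist(lapply(components, `[[`, "b")) +
    unlist(lapply(components, `[[`, "c"))
  dpos <- unlist(lapply(dxy, `[[`, "position"))
  dval <- unlist(lapply(dxy, `[[`, "dxy"))
  pos_all <- sort(unique(pos))
  ok <- !is.na(a)
  pos <- pos[ok]; a <- a[ok]; den <- den[ok]
  o <- order(pos); pos <- pos[o]; a <- a[o]; den <- den[o]
  okd <- !is.na(dval)
  dpos <- dpos[okd]; dval <- dval[okd]
  od <- order(dpos); dpos <- dpos[od]; dval <- dval[od]
  ca <- c(0, cumsum(a)); cden <- c(0, cumsum(den))
  cd <- c(0, cumsum(dval))
  n <- nrow(windows)
  theta <- dxy_mean <- rep(NA_real_, n)
  coverage <- numeric(n)
  n_positions <- integer(n)
  sum_num <- sum_den <- numeric(n)
  size <- if (n) windows$end[1] - windows$start[1] + 1L else 0L
  for (w in seq_len(n)) {
    i0 <- findInterval(windows$start[w] - 1L, pos)
    i1 <- findInterval(windows$end[w], pos)
    # distinct positions with estimates (a group lists each position once
    # per member pair)
    np <- if (i1 > i0) length(unique(pos[(i0 + 1L):i1])) else 0L
    n_positions[w] <- np
    if (denominator == "bp") {
      coverage[w] <- np / size
    } else {
      k0 <- findInterval(windows$start[w] - 1L, pos_all)
      k1 <- findInterval(windows$end[w], pos_all)
      coverage[w] <- if (k1 > k0) np / (k1 - k0) else 0
    }
    sum_num[w] <- ca[i1 + 1L] - ca[i0 + 1L]
    sum_den[w] <- cden[i1 + 1L] - cden[i0 + 1L]
    if (coverage[w] >= min_coverage && sum_den[w] != 0)
      theta[w] <- sum_num[w] / sum_den[w]
    j0 <- findInterval(windows$start[w] - 1L, dpos)
    j1 <- findInterval(windows$end[w], dpos)
    if (coverage[w] >= min_coverage && j1 > j0)
      dxy_mean[w] <- (cd[j1 + 1L] - cd[j0 + 1L]) / (j1 - j0)
  }
  cbind(windows, data.frame(theta = theta, dxy_mean = dxy_mean,
                            coverage = coverage, n_positions = n_positions,
                            sum_num = sum_num, sum_den = sum_den))
}
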
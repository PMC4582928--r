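# per-population allele bookkeeping: for each site, the number of genotyped
# diploids, and per allele index the allele count and the count of
# individuals heterozygous for that allele
allele_counts <- function(G, idx, k_max) {
  a1 <- G$a1[, idx, drop = FALSE]
  a2 <- G$a2[, idx, drop = FALSE]
  n <- rowSums(!is.na(a1))
  cnt <- het <- matrix(0, n_sites(G), k_max)
  for (k in seq_len(k_max)) {
    m1 <- a1 == k
    m2 <- a2 == k
    cnt[, k] <- rowSums(m1, na.rm = TRUE) + rowSums(m2, na.rm = TRUE)
    het[, k] <- rowSums(xor(m1, m2), na.rm = TRUE)
  }
  list(n = n, cnt = cnt, het = het)
}

#' Per-site Weir--Cockerham variance components
#'
#' Computes, for every site, the two-population random-effects variance
#' components of Weir & Cockerham's 1984 diploid model: `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals, i.e. half the average observed heterozygosity). Components
#' are computed per allele from observed heterozygosity with the
#' unequal-sample-size corrections and summed over the site's alleles, so
#' multiallelic sites are handled without splitting. The per-site estimator
#' is `a / (a + b + c)`; multi-site estimates must combine components by the
#' ratio-of-sums rule (see [multilocus_theta()]), never by averaging
#' per-site ratios.
#'
#' Sample allele frequencies use non-missing calls only, so per-site sample
#' sizes vary with missingness. A site is `defined` when both populations
#' have at least one genotyped individual and more than two genotyped
#' individuals in total (with exactly one per population the
#' within-population mean squares do not exist). Negative `a` or `b` are
#' retained: truncating them at zero would bias the ratio of sums. A site
#' monomorphic across both populations has `a = b = c = 0` and so
#' contributes nothing to either sum.
#'
#' @param G a [genotype_matrix()], already filtered for missingness.
#' @param popA,popB disjoint sample-id vectors.
#' @return data.frame of class `site_components` with columns `position`,
#'   `a`, `b`, `c`, `n_alleles`, `defined`, `n_A`, `n_B`; the contig is kept
#'   in attribute `contig`.
#' @export
site_components <- function(G, popA, popB) {
  ia <- sample_index(G, popA, "popA sample")
  ib <- sample_index(G, popB, "popB sample")
  if (length(intersect(ia, ib))) stop("popA and popB overlap")
  k_site <- lengths(G$alleles)
  k_max <- if (n_sites(G)) max(k_site) else 1L
  A <- allele_counts(G, ia, k_max)
  B <- allele_counts(G, ib, k_max)
  n1 <- A$n; n2 <- B$n
  defined <- n1 >= 1L & n2 >= 1L & (n1 + n2) > 2L
  nbar <- (n1 + n2) / 2
  nc <- ifelse(n1 + n2 > 0, 2 * n1 * n2 / (n1 + n2), NA_real_)
  a <- b <- cc <- numeric(n_sites(G))
  for (k in seq_len(k_max)) {
    p1 <- ifelse(n1 > 0, A$cnt[, k] / (2 * n1), 0)
    p2 <- ifelse(n2 > 0, B$cnt[, k] / (2 * n2), 0)
    h1 <- ifelse(n1 > 0, A$het[, k] / n1, 0)
    h2 <- ifelse(n2 > 0, B$het[, k] / n2, 0)
    pbar <- ifelse(n1 + n2 > 0, (n1 * p1 + n2 * p2) / (n1 + n2), 0)
    s2 <- ifelse(nbar > 0,
                 (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar, 0)
    hbar <- ifelse(n1 + n2 > 0, (n1 * h1 + n2 * h2) / (n1 + n2), 0)
    # r = 2 populations: (r-1)/r = 1/2
    inner <- pbar * (1 - pbar) - s2 / 2 - hbar / 4
    a <- a + (nbar / nc) * (s2 - inner / (nbar - 1))
    b <- b + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- cc + hbar / 2
  }
  a[!defined] <- NA_real_; b[!defined] <- NA_real_; cc[!defined] <- NA_real_
  out <- data.frame(position = G$positions, a = a, b = b, c = cc,
                    n_alleles = k_site, defined = defined,
                    n_A = n1, n_B = n2)
  attr(out, "contig") <- G$contig
  class(out) <- c("site_components", class(out))
  out
}

#' Per-site absolute divergence d_xy
#'
#' For each site, the probability that one allele drawn from population X
#' and one drawn from population Y differ: `dxy = 1 - sum_i x_i * y_i` over
#' sample allele frequencies `x`, `y` computed from non-missing calls. A
#' shared monomorphic site gives 0, a fixed difference gives 1.
#'
#' @inheritParams site_components
#' @return data.frame with columns `position`, `dxy`, `defined`; contig in
#'   attribute `contig`.
#' @export
site_dxy <- function(G, popA, popB) {
  ia <- sample_index(G, popA, "popA sample")
  ib <- sample_index(G, popB, "popB sample")
  if (length(intersect(ia, ib))) stop("popA and popB overlap")
  k_max <- if (n_sites(G)) max(lengths(G$alleles)) else 1L
  A <- allele_counts(G, ia, k_max)
  B <- allele_counts(G, ib, k_max)
  defined <- A$n >= 1L & B$n >= 1L
  same <- numeric(n_sites(G))
  for (k in seq_len(k_max))
    same <- same + ifelse(defined,
                          (A$cnt[, k] / (2 * A$n)) * (B$cnt[, k] / (2 * B$n)),
                          NA_real_)
  out <- data.frame(position = G$positions, dxy = 1 - same, defined = defined)
  attr(out, "contig") <- G$contig
  out
}

#' Multi-site theta-hat by the ratio-of-sums rule
#'
#' The combined relative-divergence estimate over a collection of sites:
#' numerators (`a`) and denominators (`a + b + c`) are each summed over the
#' defined sites and then divided. Monomorphic sites add 0 to both sums and
#' so leave the estimate unchanged -- unlike the mean d_xy, which they
#' dilute. A zero summed denominator yields `NA` with `undefined = TRUE`,
#' never a silent 0.
#'
#' @param components a `site_components` data.frame, or a list of them (all
#'   rows pooled into a single ratio of sums).
#' @param comparison_id label carried into the result.
#' @return list of class `divergence_estimate` with `comparison_id`,
#'   `theta`, `undefined`, `n_positions` (count of defined sites, including
#'   monomorphic ones), `sum_num`, `sum_den`.
#' @export
multilocus_theta <- function(components, comparison_id = "comparison") {
  if (inherits(components, "site_components")) components <- list(components)
  a <- unlist(lapply(components, `[[`, "a"))
  den <- a + unlist(lapply(components, `[[`, "b")) +
    unlist(lapply(components, `[[`, "c"))
  ok <- !is.na(a) & !is.na(den)
  sum_num <- sum(a[ok]); sum_den <- sum(den[ok])
  undefined <- sum(ok) == 0L || sum_den == 0
  structure(
    list(comparison_id = comparison_id,
         theta = if (undefined) NA_real_ else sum_num / sum_den,
         undefined = undefined, n_positions = sum(ok),
         sum_num = sum_num, sum_den = sum_den),
    class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("%s: theta = %s over %d positions\n", x$comparison_id,
              if (x$undefined) "undefined" else sprintf("%.4f", x$theta),
              x$n_positions))
  invisible(x)
}

#' Mean absolute divergence over defined positions
#'
#' The combining rule for d_xy is the arithmetic mean over all defined
#' positions; monomorphic positions legitimately contribute 0.
#'
#' @param dxy a data.frame from [site_dxy()], or a list of them (pooled).
#' @return scalar mean, `NA` when no position is defined.
#' @export
mean_dxy <- function(dxy) {
  if (is.data.frame(dxy)) dxy <- list(dxy)
  v <- unlist(lapply(dxy, `[[`, "dxy"))
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Combine divergence estimates across the comparisons of a group
#'
#' Groups (for example the nine allopatric postman-vs-rayed pairs) are
#' combined by summing Weir--Cockerham numerators and denominators over all
#' sites of all member comparisons -- a single pooled ratio of sums --
#' while d_xy is combined as the mean across comparisons of per-comparison
#' means.
#'
#' @param components_list list of `site_components`, one per member pair.
#' @param dxy_list optional list of [site_dxy()] frames, same order.
#' @param comparison_id group label.
#' @return `divergence_estimate` with an extra `dxy_mean` element when
#'   `dxy_list` is given.
#' @export
combine_group <- function(components_list, dxy_list = NULL,
                          comparison_id = "group") {
  if (!length(components_list)) stop("empty comparison group")
  est <- multilocus_theta(components_list, comparison_id)
  if (!is.null(dxy_list))
    est$dxy_mean <- mean(vapply(dxy_list, mean_dxy, numeric(1)))
  est
}

#' Percentile bootstrap CI for theta-hat or mean d_xy
#'
#' Resamples positions with replacement (as many as observed) from the
#' pooled defined sites, recomputes the statistic for each replicate and
#' takes percentile bounds. For theta the resampled statistic is the ratio
#' of sums; for dxy it is the mean. With all-identical sites the CI
#' collapses to the point estimate. Fully reproducible under `seed`.
#'
#' @param components a `site_components` frame (or list, pooled) for
#'   `statistic = "theta"`; a [site_dxy()] frame (or list) for `"dxy"`.
#' @param statistic `"theta"` or `"dxy"`.
#' @param n_reps bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer RNG seed.
#' @return list of class `bootstrap_ci`: `lower`, `upper`, `point`,
#'   `level`, `n_reps`, `seed`, `statistic`.
#' @export
bootstrap_ci <- function(components, statistic = c("theta", "dxy"),
                         n_reps = 1000L, level = 0.95, seed = 1L) {
  statistic <- match.arg(statistic)
  if (is.data.frame(components)) components <- list(components)
  if (statistic == "theta") {
    a <- unlist(lapply(components, `[[`, "a"))
    den <- a + unlist(lapply(components, `[[`, "b")) +
      unlist(lapply(components, `[[`, "c"))
    ok <- !is.na(a)
    num <- a[ok]; den <- den[ok]
    point <- sum(num) / sum(den)
  } else {
    v <- unlist(lapply(components, `[[`, "dxy"))
    num <- v[!is.na(v)]
    den <- rep(1, length(num))
    point <- mean(num)
  }
  n <- length(num)
  if (n < 2L) stop("bootstrap needs at least 2 defined sites")
  stat <- numeric(n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      w <- tabulate(sample.int(n, n, replace = TRUE), n)
      stat[r] <- sum(w * num) / sum(w * den)
    }
  })
  qs <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(lower = qs[1], upper = qs[2], point = point, level = level,
                 n_reps = n_reps, seed = seed, statistic = statistic),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%s = %.4f, %d%% CI = %.4f-%.4f (%d bootstrap reps)\n",
              x$statistic, x$point, round(100 * x$level), x$lower, x$upper,
              x$n_reps))
  invisible(x)
}
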
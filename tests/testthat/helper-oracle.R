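# Independent scalar transcription of the Weir & Cockerham (1984)
# variance-component equations for r populations of diploids, written as
# explicit loops over populations and alleles so it shares no code path
# with site_components(). Input: a list of populations, each a list of
# genotypes, each genotype an integer pair of allele indices (or NULL for
# missing).
oracle_wc_site <- function(pops) {
  pops <- lapply(pops, function(p) Filter(Negate(is.null), p))
  r <- length(pops)
  n <- vapply(pops, length, integer(1))
  if (any(n < 1L) || sum(n) <= r) return(list(a = NA_real_, b = NA_real_,
                                              c = NA_real_))
  alleles <- sort(unique(unlist(pops)))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  a_tot <- b_tot <- c_tot <- 0
  for (al in alleles) {
    p_i <- numeric(r)
    h_i <- numeric(r)
    for (i in seq_len(r)) {
      cnt <- 0L; het <- 0L
      for (g in pops[[i]]) {
        cnt <- cnt + sum(g == al)
        if (sum(g == al) == 1L) het <- het + 1L
      }
      p_i[i] <- cnt / (2 * n[i])
      h_i[i] <- het / n[i]
    }
    pbar <- sum(n * p_i) / (r * nbar)
    s2 <- sum(n * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h_i) / (r * nbar)
    a_tot <- a_tot + (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_tot <- b_tot + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_tot <- c_tot + hbar / 2
  }
  list(a = a_tot, b = b_tot, c = c_tot)
}

# dxy by exhaustive enumeration of cross-population allele draws -- an
# independent route to the 1 - sum(x_i * y_i) frequency formula
oracle_dxy_site <- function(popA, popB) {
  aA <- unlist(Filter(Negate(is.null), popA))
  aB <- unlist(Filter(Negate(is.null), popB))
  if (!length(aA) || !length(aB)) return(NA_real_)
  diff <- 0L
  for (x in aA) for (y in aB) diff <- diff + (x != y)
  diff / (length(aA) * length(aB))
}

# random small instance generator for oracle-equivalence checks
random_instance <- function(max_n = 6L, max_alleles = 3L,
                            missing_rate = 0.15) {
  nA <- sample(1:max_n, 1L); nB <- sample(1:max_n, 1L)
  k <- sample(2:max_alleles, 1L)
  draw <- function(n) lapply(seq_len(n), function(i) {
    if (stats::runif(1) < missing_rate) NULL
    else sample.int(k, 2L, replace = TRUE)
  })
  list(popA = draw(nA), popB = draw(nB), k = k)
}

# pack an instance into a genotype_matrix at a single site
instance_to_gm <- function(inst, position = 1L) {
  gens <- c(inst$popA, inst$popB)
  a1 <- vapply(gens, function(g) if (is.null(g)) NA_integer_ else g[1L],
               integer(1))
  a2 <- vapply(gens, function(g) if (is.null(g)) NA_integer_ else g[2L],
               integer(1))
  samples <- c(paste0("A", seq_along(inst$popA)),
               paste0("B", seq_along(inst$popB)))
  genotype_matrix("oracle", position, list(c("A", "C", "G")[seq_len(inst$k)]),
                  matrix(a1, 1L), matrix(a2, 1L), samples)
}
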
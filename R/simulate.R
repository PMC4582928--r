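#' Configuration of the synthetic hybrid-zone generator
#'
#' Describes a pair of diverging diploid populations on one contig. Per
#' site, an ancestral allele frequency is drawn uniformly, each population's
#' frequency is drawn from the Balding--Nichols Beta distribution around it
#' with divergence parameter `F`, and genotypes are drawn in Hardy--Weinberg
#' proportions within populations. `F` varies along the contig as a low
#' baseline plus a peak decaying exponentially with recombination distance
#' from a causative site -- the hybrid-zone genome-scan situation the
#' pipeline is built for (a near-zero genomic background with a sharp
#' divergence peak over the functional region).
#'
#' Defaults give a 1-Mb contig carrying 50,000 SNPs (the empirical density
#' of segregating sites in these scans is of order 0.05--0.1 per bp), 10
#' diploids per population (within the study's 4--14 per-taxon range),
#' baseline `F_bg = 0.02` against peak `F_pk = 0.9` with a 0.5 cM decay
#' scale, and 10% per-genotype missingness.
#'
#' @param n_per_pop diploid individuals per population.
#' @param n_sites number of SNP sites, placed uniformly without replacement.
#' @param contig_length contig length in bp.
#' @param ancestral_freq_range uniform range for ancestral frequencies.
#' @param F_bg baseline divergence parameter in (0, 1).
#' @param F_pk peak divergence parameter, `F_bg <= F_pk <= 1`.
#' @param peak_center bp coordinate of the causative site.
#' @param lambda_cM exponential decay scale of the peak, in cM.
#' @param missing_rate independent per-genotype missingness probability.
#' @param triallelic_rate fraction of sites given a third allele (default 0;
#'   exercises the multi-allele estimator path).
#' @param recomb a [recombination_model()].
#' @param contig contig name.
#' @param seed integer seed; the same seed gives byte-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_pop = 10L, n_sites = 50000L,
                       contig_length = 1000000L,
                       ancestral_freq_range = c(0.05, 0.95),
                       F_bg = 0.02, F_pk = 0.9,
                       peak_center = 500000L, lambda_cM = 0.5,
                       missing_rate = 0.1, triallelic_rate = 0,
                       recomb = recombination_model(),
                       contig = "sim_contig", seed = 1L) {
  cfg <- structure(
    list(n_per_pop = as.integer(n_per_pop), n_sites = as.integer(n_sites),
         contig_length = as.integer(contig_length),
         ancestral_freq_range = ancestral_freq_range,
         F_bg = F_bg, F_pk = F_pk, peak_center = as.integer(peak_center),
         lambda_cM = lambda_cM, missing_rate = missing_rate,
         triallelic_rate = triallelic_rate, recomb = recomb,
         contig = contig, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!(F_bg > 0 && F_bg <= F_pk && F_pk <= 1))
      stop("need 0 < F_bg <= F_pk <= 1")
    if (missing_rate < 0 || missing_rate >= 1)
      stop("need 0 <= missing_rate < 1")
    if (n_sites > contig_length)
      stop("n_sites exceeds contig_length")
    if (n_per_pop < 1L) stop("need at least 1 diploid per population")
    rng <- ancestral_freq_range
    if (length(rng) != 2L || rng[1] <= 0 || rng[2] >= 1 || rng[1] > rng[2])
      stop("ancestral_freq_range must lie strictly inside (0, 1)")
    if (lambda_cM <= 0) stop("lambda_cM must be positive")
  })
  cfg
}

#' Target divergence along the contig
#'
#' `F(x) = F_bg + (F_pk - F_bg) * exp(-d(x) / lambda_cM)` where `d(x)` is
#' the recombination distance from the causative site. At the peak centre
#' it equals `F_pk`; far away it tends to `F_bg`.
#'
#' @param position bp coordinate(s).
#' @param config a [sim_config()].
#' @return target F value(s) in (0, 1].
#' @export
divergence_profile <- function(position, config) {
  d <- bp_to_cM(abs(position - config$peak_center), config$recomb)
  config$F_bg + (config$F_pk - config$F_bg) * exp(-d / config$lambda_cM)
}

# vectorized biallelic Balding-Nichols draw: Beta(p(1-F)/F, (1-p)(1-F)/F);
# at F ~ 1 the Beta degenerates to fixation with probability p
rbeta_bn <- function(p, F) {
  out <- numeric(length(p))
  deg <- F >= 1 - 1e-12
  if (any(!deg)) {
    s <- (1 - F[!deg]) / F[!deg]
    out[!deg] <- stats::rbeta(sum(!deg), p[!deg] * s, (1 - p[!deg]) * s)
  }
  if (any(deg))
    out[deg] <- as.numeric(stats::runif(sum(deg)) < p[deg])
  out
}

# Balding-Nichols population frequencies for one site: Dirichlet with
# parameters p_k (1-F)/F around the ancestral frequency vector p
bn_freq <- function(p, F) {
  g <- stats::rgamma(length(p), shape = p * (1 - F) / F)
  if (all(g == 0)) g[which.max(p)] <- 1   # numerically degenerate draw
  g / sum(g)
}

#' Simulate a diverged population pair
#'
#' Draws the full synthetic dataset described by `config` and returns both
#' the genotype matrix and the generating truth (ancestral and realized
#' allele frequencies and the per-site target F), sufficient to compute
#' analytic expectations for every estimator. Samples are named
#' `popA_1..n` and `popB_1..n`.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes` (a [genotype_matrix()]), `truth`
#'   (data.frame: `position`, `p_anc`, `p_popA`, `p_popB` -- reference-allele
#'   frequencies -- `F_target`, `n_alleles`) and `config`.
#' @export
simulate_pair <- function(config) {
  validate_sim_config(config)
  n <- config$n_per_pop
  samples <- c(paste0("popA_", seq_len(n)), paste0("popB_", seq_len(n)))
  with_seed(config$seed, {
    positions <- sort(sample.int(config$contig_length, config$n_sites))
    Fx <- divergence_profile(positions, config)
    p_anc <- stats::runif(config$n_sites, config$ancestral_freq_range[1],
                          config$ancestral_freq_range[2])
    tri <- stats::runif(config$n_sites) < config$triallelic_rate
    k_site <- ifelse(tri, 3L, 2L)
    a1 <- a2 <- matrix(NA_integer_, config$n_sites, 2L * n)
    pA_ref <- pB_ref <- numeric(config$n_sites)
    base4 <- c("A", "C", "G", "T")
    alleles <- vector("list", config$n_sites)
    bi <- which(!tri)
    if (length(bi)) {
      # vectorized Balding-Nichols Beta draws for the biallelic sites;
      # F numerically at 1 degenerates to fixation of one or other allele
      pA_ref[bi] <- rbeta_bn(p_anc[bi], Fx[bi])
      pB_ref[bi] <- rbeta_bn(p_anc[bi], Fx[bi])
      nb <- length(bi)
      ga1 <- matrix(stats::runif(nb * n) >= pA_ref[bi], nb, n)
      ga2 <- matrix(stats::runif(nb * n) >= pA_ref[bi], nb, n)
      gb1 <- matrix(stats::runif(nb * n) >= pB_ref[bi], nb, n)
      gb2 <- matrix(stats::runif(nb * n) >= pB_ref[bi], nb, n)
      a1[bi, ] <- cbind(ga1, gb1) + 1L
      a2[bi, ] <- cbind(ga2, gb2) + 1L
    }
    for (s in which(tri)) {
      rest <- 1 - p_anc[s]
      w <- stats::runif(1, 0.5, 0.9)
      pv <- c(p_anc[s], rest * w, rest * (1 - w))
      xa <- bn_freq(pv, Fx[s])
      xb <- bn_freq(pv, Fx[s])
      pA_ref[s] <- xa[1]; pB_ref[s] <- xb[1]
      ga <- sample.int(3L, 2L * n, replace = TRUE, prob = xa)
      gb <- sample.int(3L, 2L * n, replace = TRUE, prob = xb)
      a1[s, ] <- c(ga[seq_len(n)], gb[seq_len(n)])
      a2[s, ] <- c(ga[n + seq_len(n)], gb[n + seq_len(n)])
    }
    alleles[tri] <- list(base4[1:3])
    alleles[!tri] <- list(base4[1:2])
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(length(a1)) < config$missing_rate,
                     nrow(a1), ncol(a1))
      a1[miss] <- NA_integer_
      a2[miss] <- NA_integer_
    }
    G <- genotype_matrix(config$contig, positions, alleles, a1, a2, samples)
    truth <- data.frame(position = positions, p_anc = p_anc,
                        p_popA = pA_ref, p_popB = pB_ref,
                        F_target = Fx, n_alleles = k_site)
    list(genotypes = G, truth = truth, config = config)
  })
}

#' Sample ids of the two simulated populations
#' @param config a [sim_config()].
#' @return list with `popA` and `popB` character vectors.
#' @export
sim_populations <- function(config) {
  n <- config$n_per_pop
  list(popA = paste0("popA_", seq_len(n)), popB = paste0("popB_", seq_len(n)))
}

#' Estimand of theta-hat for a simulated region
#'
#' The multi-site ratio-of-sums theta converges to a weighted average of the
#' per-site target F, weighted by each site's expected total variance
#' (proportional to the ancestral heterozygosity `p(1-p)`). With realized
#' truth available the weights use the drawn ancestral frequencies; without
#' it, ancestral frequency is independent of position, the weights cancel
#' in expectation, and the estimand reduces to the average of the
#' divergence profile over the region, computed by numerical quadrature.
#'
#' @param config a [sim_config()].
#' @param region_start,region_end interval bounds (default: whole contig).
#' @param truth optional truth frame from [simulate_pair()] for
#'   realized-site weighting.
#' @return scalar estimand.
#' @export
expected_theta <- function(config, region_start = 1L,
                           region_end = config$contig_length, truth = NULL) {
  if (!is.null(truth)) {
    inside <- truth$position >= region_start & truth$position <= region_end
    w <- truth$p_anc[inside] * (1 - truth$p_anc[inside])
    return(sum(w * truth$F_target[inside]) / sum(w))
  }
  f <- function(x) divergence_profile(x, config)
  stats::integrate(f, region_start, region_end, rel.tol = 1e-9)$value /
    (region_end - region_start)
}
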
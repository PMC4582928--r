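test_that("fixed differences and shared monomorphism hit the exact bounds", {
  # popA all hom ref (n=2), popB all hom alt (n=2)
  G <- gm(c("0/0", "0/0", "1/1", "1/1"))
  popA <- c("s1", "s2"); popB <- c("s3", "s4")
  comp <- site_components(G, popA, popB)
  expect_equal(comp$a / (comp$a + comp$b + comp$c), 1)
  expect_equal(site_dxy(G, popA, popB)$dxy, 1)
  # identical monomorphic populations contribute nothing
  G0 <- gm(c("0/0", "0/0", "0/0", "0/0"))
  comp0 <- site_components(G0, popA, popB)
  expect_equal(c(comp0$a, comp0$b, comp0$c), c(0, 0, 0))
  expect_equal(site_dxy(G0, popA, popB)$dxy, 0)
})

test_that("components match the independent 1984 transcription ({AA,Aa} vs {aa,aa})", {
  G <- gm(c("0/0", "0/1", "1/1", "1/1"))
  comp <- site_components(G, c("s1", "s2"), c("s3", "s4"))
  orc <- oracle_wc_site(list(list(c(1L, 1L), c(1L, 2L)),
                             list(c(2L, 2L), c(2L, 2L))))
  expect_equal(comp$a, orc$a, tolerance = 1e-12)
  expect_equal(comp$b, orc$b, tolerance = 1e-12)
  expect_equal(comp$c, orc$c, tolerance = 1e-12)
})

test_that("oracle equivalence holds across random small instances", {
  set.seed(424)
  for (i in 1:300) {
    inst <- random_instance()
    G <- instance_to_gm(inst)
    comp <- site_components(G, paste0("A", seq_along(inst$popA)),
                            paste0("B", seq_along(inst$popB)))
    orc <- oracle_wc_site(list(inst$popA, inst$popB))
    expect_equal(comp$a, orc$a, tolerance = 1e-12)
    expect_equal(comp$b, orc$b, tolerance = 1e-12)
    expect_equal(comp$c, orc$c, tolerance = 1e-12)
    dx <- site_dxy(G, paste0("A", seq_along(inst$popA)),
                   paste0("B", seq_along(inst$popB)))
    orc_d <- oracle_dxy_site(inst$popA, inst$popB)
    if (is.na(orc_d)) expect_true(is.na(dx$dxy))
    else expect_equal(dx$dxy, orc_d, tolerance = 1e-12)
  }
})

test_that("dxy follows the allele-frequency form", {
  # x = y = (0.5, 0.5) -> 0.5
  G <- gm(c("0/1", "0/1", "0/1", "0/1"))
  expect_equal(site_dxy(G, c("s1", "s2"), c("s3", "s4"))$dxy, 0.5)
})

test_that("multilocus theta is a ratio of sums, not a mean of ratios", {
  comp <- data.frame(position = c(10L, 20L), a = c(1, 1), b = c(1, 3),
                     c = c(0, 0), n_alleles = 2L, defined = TRUE,
                     n_A = 4L, n_B = 4L)
  class(comp) <- c("site_components", class(comp))
  est <- multilocus_theta(comp)
  expect_equal(est$theta, 2 / 6)       # mean of ratios would be 0.375
  expect_equal(est$n_positions, 2L)
})

test_that("monomorphic sites leave theta unchanged but dilute mean dxy", {
  G <- gm(c("0/0", "0/0", "1/1", "1/1"), c("0/0", "0/0", "0/0", "0/0"))
  popA <- c("s1", "s2"); popB <- c("s3", "s4")
  comp <- site_components(G, popA, popB)
  est <- multilocus_theta(comp)
  expect_equal(est$theta, 1)           # 99 more monomorphic sites: still 1
  expect_equal(est$n_positions, 2L)    # monomorphic sites still count
  expect_equal(mean_dxy(site_dxy(G, popA, popB)), 0.5)
})

test_that("zero summed denominator is flagged undefined, not silently 0", {
  G <- gm(c("0/0", "0/0", "0/0", "0/0"))
  est <- multilocus_theta(site_components(G, c("s1", "s2"), c("s3", "s4")))
  expect_true(est$undefined)
  expect_true(is.na(est$theta))
})

test_that("theta and dxy are invariant to swapping population labels", {
  cfg <- test_sim_config(seed = 77L, missing_rate = 0.2)
  sim <- simulate_pair(cfg)
  pops <- sim_populations(cfg)
  G <- subset_sites(sim$genotypes,
                    filter_pair_missingness(sim$genotypes, pops$popA,
                                            pops$popB))
  cAB <- site_components(G, pops$popA, pops$popB)
  cBA <- site_components(G, pops$popB, pops$popA)
  expect_equal(cAB$a, cBA$a, tolerance = 1e-12)
  expect_equal(cAB$b, cBA$b, tolerance = 1e-12)
  expect_equal(site_dxy(G, pops$popA, pops$popB)$dxy,
               site_dxy(G, pops$popB, pops$popA)$dxy, tolerance = 1e-12)
})

test_that("mean dxy matches the analytic value from simulator truth", {
  cfg <- test_sim_config(n_sites = 3000L, contig_length = 100000L,
                         missing_rate = 0, seed = 31L)
  sim <- simulate_pair(cfg)
  pops <- sim_populations(cfg)
  dx <- site_dxy(sim$genotypes, pops$popA, pops$popB)
  # conditional on realized frequencies, E[dxy_site] = 1 - xa*xb - (1-xa)(1-xb)
  expected <- mean(1 - sim$truth$p_popA * sim$truth$p_popB -
                   (1 - sim$truth$p_popA) * (1 - sim$truth$p_popB))
  expect_lt(abs(mean_dxy(dx) - expected), 0.01)
})

test_that("group combining equals one pooled ratio of sums", {
  set.seed(99)
  comps <- lapply(1:9, function(i) {
    cfg <- test_sim_config(n_sites = 200L, contig_length = 20000L,
                           seed = 100L + i)
    sim <- simulate_pair(cfg)
    pops <- sim_populations(cfg)
    site_components(sim$genotypes, pops$popA, pops$popB)
  })
  grp <- combine_group(comps, comparison_id = "g9")
  # brute-force pooled ratio over every defined site of every member
  num <- den <- 0
  for (cmp in comps) for (i in seq_len(nrow(cmp))) {
    if (!is.na(cmp$a[i])) {
      num <- num + cmp$a[i]
      den <- den + cmp$a[i] + cmp$b[i] + cmp$c[i]
    }
  }
  expect_equal(grp$theta, num / den, tolerance = 1e-12)
  expect_equal(combine_group(comps[1], comparison_id = "one")$theta,
               multilocus_theta(comps[[1]])$theta)
})

test_that("bootstrap CIs are deterministic under seed and collapse when degenerate", {
  comp <- data.frame(position = 1:20 * 10L, a = rep(0.3, 20),
                     b = rep(0.5, 20), c = rep(0.2, 20), n_alleles = 2L,
                     defined = TRUE, n_A = 5L, n_B = 5L)
  class(comp) <- c("site_components", class(comp))
  ci <- bootstrap_ci(comp, "theta", n_reps = 100L, seed = 3L)
  expect_equal(ci$lower, ci$point)
  expect_equal(ci$upper, ci$point)
  cfg <- test_sim_config(seed = 55L)
  sim <- simulate_pair(cfg)
  pops <- sim_populations(cfg)
  cm <- site_components(sim$genotypes, pops$popA, pops$popB)
  ci1 <- bootstrap_ci(cm, "theta", 200L, 0.95, seed = 17L)
  ci2 <- bootstrap_ci(cm, "theta", 200L, 0.95, seed = 17L)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$point)
  expect_gte(ci1$upper, ci1$point)
  ci3 <- bootstrap_ci(cm, "theta", 200L, 0.95, seed = 18L)
  expect_false(identical(ci1$lower, ci3$lower))
})
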
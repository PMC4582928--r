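write_fixture_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

fixture_3samp <- function() {
  write_fixture_vcf(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=ctg1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "ctg1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/0\t0/1\t./.",
    "ctg1\t200\t.\tA\tC,T\t.\t.\t.\tGT\t0|2\t1/1\t0/0"))
}

test_that("VCF read-back preserves calls, missingness and multiallelic sites", {
  mats <- read_genotypes(fixture_3samp(), c("s1", "s2", "s3"))
  expect_named(mats, "ctg1")
  G <- mats$ctg1
  expect_equal(G$positions, c(100L, 200L))
  expect_equal(sum(is.na(G$a1)), 1L)             # exactly the ./. call
  expect_true(is.na(G$a1[1, "s3"]))
  expect_equal(G$alleles[[2]], c("A", "C", "T")) # 3 alleles retained
  expect_equal(unname(G$a1[2, ]), c(1L, 2L, 1L)) # phased parsed as unordered
  expect_equal(unname(G$a2[2, ]), c(3L, 2L, 1L))
})

test_that("metadata samples absent from the VCF are a named hard error", {
  expect_error(read_genotypes(fixture_3samp(), c("s1", "s9")), "s9")
})

test_that("malformed VCF records error with a line number", {
  bad <- write_fixture_vcf(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "ctg1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/0",
    "ctg1\t200\t.\tA\tT\t.\t.\tGT\t0/0"))
  expect_error(read_genotypes(bad), "line 4")
  bad2 <- write_fixture_vcf(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "ctg1\toops\t.\tA\tT\t.\t.\t.\tGT\t0/0"))
  expect_error(read_genotypes(bad2), "line 3")
})

test_that("indels and half-calls are dropped/missing at read time", {
  p <- write_fixture_vcf(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "ctg1\t10\t.\tAT\tA\t.\t.\t.\tGT\t0/0\t0/1",
    "ctg1\t20\t.\tA\tT\t.\t.\t.\tGT\t./0\t0/1",
    "ctg1\t30\t.\tG\t*\t.\t.\t.\tGT\t0/0\t0/0"))
  G <- read_genotypes(p)$ctg1
  expect_equal(G$positions, 20L)                 # indel + spanning del gone
  expect_true(is.na(G$a1[1, "s1"]) && is.na(G$a2[1, "s1"]))
  expect_equal(G$a1[1, "s2"], c(s2 = 1L))
})

test_that("synthetic VCF round-trips through write_vcf/read_genotypes", {
  cfg <- test_sim_config(triallelic_rate = 0.1, seed = 11L)
  sim <- simulate_pair(cfg)
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, path, cfg$contig_length)
  back <- read_genotypes(path, sim$genotypes$samples)[[cfg$contig]]
  expect_identical(back$positions, sim$genotypes$positions)
  expect_identical(back$alleles, sim$genotypes$alleles)
  expect_identical(unname(back$a1), unname(sim$genotypes$a1))
  expect_identical(unname(back$a2), unname(sim$genotypes$a2))
})

test_that("pair missingness filter honours the 75% boundary per population", {
  # popA n=4: sites with 3/4 (=0.75, kept), 4/4 (kept); popB complete
  G <- gm(c("0/0", "0/1", "1/1", "./.", "0/0", "0/0"),
          c("0/0", "0/1", "1/1", "0/0", "0/0", "0/0"))
  popA <- paste0("s", 1:4); popB <- paste0("s", 5:6)
  expect_equal(filter_pair_missingness(G, popA, popB), c(TRUE, TRUE))
  # popA n=5 with 3 genotyped (0.6) at site 1 -> dropped
  G2 <- gm(c("0/0", "0/1", "1/1", "./.", "./.", "0/0", "0/0"),
           c("0/0", "0/1", "1/1", "0/0", "0/0", "0/0", "0/0"))
  expect_equal(filter_pair_missingness(G2, paste0("s", 1:5), paste0("s", 6:7)),
               c(FALSE, TRUE))
  expect_error(filter_pair_missingness(G, character(0), popB), "empty")
  expect_error(filter_pair_missingness(G, popA, c("s4", "s5")), "overlap")
})

test_that("missingness filter matches the binomial expectation", {
  m <- 0.2; n <- 10L
  cfg <- test_sim_config(n_per_pop = n, n_sites = 4000L,
                         contig_length = 200000L, missing_rate = m,
                         seed = 23L)
  sim <- simulate_pair(cfg)
  pops <- sim_populations(cfg)
  kept <- mean(filter_pair_missingness(sim$genotypes, pops$popA, pops$popB))
  p_pop <- sum(stats::dbinom(8:10, n, 1 - m))  # >= 75% of 10 genotyped
  expect_lt(abs(kept - p_pop^2), 4 * sqrt(p_pop^2 * (1 - p_pop^2) / 4000))
})

test_that("filters behave as masks: idempotent and symmetric", {
  cfg <- test_sim_config(n_sites = 300L, missing_rate = 0.3, seed = 5L)
  sim <- simulate_pair(cfg)
  pops <- sim_populations(cfg)
  k1 <- filter_pair_missingness(sim$genotypes, pops$popA, pops$popB)
  expect_identical(k1, filter_pair_missingness(sim$genotypes, pops$popB,
                                               pops$popA))
  G2 <- subset_sites(sim$genotypes, k1)
  k2 <- filter_pair_missingness(G2, pops$popA, pops$popB)
  expect_true(all(k2))
  expect_identical(subset_sites(G2, k2), G2)
})

test_that("invariant-site removal sees variation only within the listed samples", {
  G <- gm(c("0/0", "0/0", "0/0", "0/0"),   # all AA -> dropped
          c("0/0", "0/1", "0/0", "0/0"),   # AA, AT -> kept
          c("0/0", "0/0", "1/1", "1/1"))   # fixed difference between halves
  all4 <- paste0("s", 1:4)
  expect_equal(remove_invariant_sites(G, all4), c(FALSE, TRUE, TRUE))
  expect_equal(remove_invariant_sites(G, c("s3", "s4"))[3], FALSE)
  expect_equal(remove_invariant_sites(G, all4)[3], TRUE)
})

test_that("subset_region keeps exactly the in-interval sites, inclusively", {
  G <- gm(c("0/0", "0/1"), c("0/0", "0/1"), c("0/0", "0/1"),
          positions = c(50L, 150L, 250L))
  expect_identical(subset_region(G, 1L, 300L), G)
  expect_equal(subset_region(G, 100L, 200L)$positions, 150L)
  expect_equal(subset_region(G, 150L, 200L)$positions, 150L)  # boundary in
  expect_equal(n_sites(subset_region(G, 151L, 200L)), 0L)     # empty ok
})

test_that("sample and region tables validate their invariants", {
  samp <- read_sample_table(system.file("extdata/samples_synthetic.tsv",
                                        package = "divscan"))
  expect_equal(nrow(samp), 58L)
  expect_setequal(unique(samp$role), c("ingroup", "outgroup"))
  reg <- read_region_table(system.file("extdata/regions_synthetic.tsv",
                                       package = "divscan"))
  expect_true(sum(reg$end[reg$is_unlinked] - reg$start[reg$is_unlinked] + 1L)
              == 350000L)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\tcontig\tstart\tend\tflags",
               "func\tc1\t10\t20\tis_functional_65kb",
               "locus\tc2\t1\t100\tis_color_locus"), bad)
  expect_error(read_region_table(bad), "not contained")
})
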
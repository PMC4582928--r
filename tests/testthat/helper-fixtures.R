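# build a genotype_matrix from compact genotype strings: one character
# vector per site, entries like "0/0", "0/1", "./."; allele indices are
# VCF-style 0-based
gm <- function(..., positions = NULL, alleles = NULL, contig = "fix",
               samples = NULL) {
  sites <- list(...)
  n_samp <- length(sites[[1L]])
  if (is.null(positions)) positions <- seq_along(sites) * 10L
  if (is.null(samples)) samples <- paste0("s", seq_len(n_samp))
  if (is.null(alleles)) alleles <- rep(list(c("A", "T")), length(sites))
  parse1 <- function(g, slot) {
    part <- strsplit(g, "/", fixed = TRUE)[[1L]][slot]
    if (part == ".") NA_integer_ else as.integer(part) + 1L
  }
  a1 <- t(vapply(sites, function(s) vapply(s, parse1, integer(1), 1L),
                 integer(n_samp)))
  a2 <- t(vapply(sites, function(s) vapply(s, parse1, integer(1), 2L),
                 integer(n_samp)))
  genotype_matrix(contig, positions, alleles, a1, a2, samples)
}

# concatenate single-contig VCFs written by write_vcf into one multi-contig
# VCF (same sample columns)
concat_vcfs <- function(paths, out) {
  all_lines <- lapply(paths, readLines)
  hdr1 <- grep("^#", all_lines[[1L]], value = TRUE)
  contigs <- unlist(lapply(all_lines, grep, pattern = "^##contig",
                           value = TRUE))
  hdr <- c(hdr1[1:2], contigs, hdr1[grep("^##FORMAT|^#CHROM", hdr1)])
  body <- unlist(lapply(all_lines, grep, pattern = "^[^#]", value = TRUE))
  writeLines(c(hdr, body), out)
  out
}

# small fast simulation config for tests
test_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(n_per_pop = 8L, n_sites = 800L, contig_length = 60000L,
                   F_bg = 0.2, F_pk = 0.2, missing_rate = 0.05,
                   peak_center = 30000L, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
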
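#' Read a sample metadata table
#'
#' Tab-separated with header columns `sample_id`, `taxon`, `hybrid_zone`,
#' `phenotype_class`, `role`. Every ingroup sample must carry a hybrid zone
#' and a phenotype class; `phenotype_class` is one of `postman`, `rayed`,
#' `himera`, `outgroup`.
#'
#' @param path TSV file path.
#' @return data.frame with the five columns, validated.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "taxon", "hybrid_zone", "phenotype_class", "role")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  validate_sample_table(tab[need])
}

validate_sample_table <- function(tab) {
  if (anyDuplicated(tab$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  ok_class <- c("postman", "rayed", "himera", "outgroup")
  bad <- setdiff(tab$phenotype_class, ok_class)
  if (length(bad))
    stop("unknown phenotype_class: ", paste(bad, collapse = ", "))
  bad <- setdiff(tab$role, c("ingroup", "outgroup"))
  if (length(bad)) stop("unknown role: ", paste(bad, collapse = ", "))
  ing <- tab$role == "ingroup"
  incomplete <- ing & (is.na(tab$hybrid_zone) | tab$hybrid_zone == "" |
                       tab$phenotype_class == "outgroup")
  if (any(incomplete))
    stop("ingroup sample(s) lack hybrid_zone/phenotype_class: ",
         paste(tab$sample_id[incomplete], collapse = ", "))
  tab
}

#' Read a named-region table
#'
#' Tab-separated with header `name`, `contig`, `start`, `end`, `flags`;
#' coordinates 1-based inclusive. `flags` is a comma-separated subset of
#' `is_color_locus`, `is_functional_65kb`, `is_unlinked` (may be empty).
#' Validates that the functional sub-interval is contained in the color-locus
#' interval and warns when the unlinked intervals stray far from the 350-kb
#' the baseline design expects.
#'
#' @param path TSV file path.
#' @return data.frame with columns name, contig, start, end and logical flag
#'   columns `is_color_locus`, `is_functional_65kb`, `is_unlinked`.
#' @export
read_region_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(flags = "character"))
  need <- c("name", "contig", "start", "end", "flags")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("region table missing column(s): ", paste(miss, collapse = ", "))
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  if (any(tab$start < 1L) || any(tab$end < tab$start))
    stop("invalid interval bounds in region table")
  flags <- strsplit(ifelse(is.na(tab$flags), "", tab$flags), ",", fixed = TRUE)
  for (f in c("is_color_locus", "is_functional_65kb", "is_unlinked"))
    tab[[f]] <- vapply(flags, function(x) f %in% trimws(x), logical(1))
  fun <- tab[tab$is_functional_65kb, , drop = FALSE]
  loc <- tab[tab$is_color_locus, , drop = FALSE]
  if (nrow(fun) && nrow(loc)) {
    inside <- any(fun$contig[1] == loc$contig & fun$start[1] >= loc$start &
                  fun$end[1] <= loc$end)
    if (!inside)
      stop("functional sub-interval '", fun$name[1],
           "' is not contained in the color-locus interval")
  }
  unl <- sum(tab$end[tab$is_unlinked] - tab$start[tab$is_unlinked] + 1L)
  if (unl > 0 && abs(unl - 350e3) / 350e3 > 0.25)
    warning("unlinked intervals total ", unl,
            " bp; the baseline design expects ~350 kb")
  tab
}

# fast structural scan of a VCF so parse failures carry a line number
check_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- startsWith(lines, "#")
  n_field <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE))) + 1L
  body <- which(!hdr & nzchar(lines))
  if (!length(body)) return(invisible(TRUE))
  expected <- n_field[body[1L]]
  bad <- body[n_field[body] != expected]
  if (length(bad))
    stop("malformed VCF record at line ", bad[1L], " of ", path,
         ": expected ", expected, " fields, found ", n_field[bad[1L]])
  pos <- suppressWarnings(as.integer(
    sub("^[^\t]*\t([^\t]*)\t.*$", "\\1", lines[body])))
  if (anyNA(pos))
    stop("malformed VCF record at line ", body[which(is.na(pos))[1L]],
         " of ", path, ": non-integer POS")
  invisible(TRUE)
}

#' Read diploid genotypes from a VCF file
#'
#' Reads a multi-sample VCF (v4.x) and returns one [genotype_matrix()] per
#' contig. Only SNPs are retained: records whose REF or any ALT allele is
#' not a single base (indels, spanning deletions `*`, symbolic alleles) are
#' dropped. Multiallelic records are kept as one site with all alleles.
#' Phased and unphased genotypes are treated alike as unordered allele
#' pairs; a half-call (for example `./0`) or a haploid call makes the whole
#' genotype missing, because downstream filters count individuals genotyped.
#' No QUAL/FILTER-based filtering is applied: site quality control is
#' assumed to be upstream.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF file.
#' @param samples optional character vector of sample ids that must be
#'   present; a listed sample absent from the VCF is a hard error naming it.
#'   When given, the matrices are restricted to these samples, in order.
#' @return named list of `genotype_matrix`, one element per contig (in
#'   order of first appearance).
#' @export
read_genotypes <- function(vcf_path, samples = NULL) {
  if (!file.exists(vcf_path)) stop("no such VCF: ", vcf_path)
  check_vcf_lines(vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  vcf_samp <- colnames(vcf)
  if (!is.null(samples)) {
    absent <- setdiff(samples, vcf_samp)
    if (length(absent))
      stop("sample(s) in metadata absent from VCF: ",
           paste(absent, collapse = ", "))
    vcf <- vcf[, samples]
  } else {
    samples <- vcf_samp
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as(rr$ALT, "CharacterList")
  snp <- nchar(ref) == 1L &
    vapply(alt, function(a) length(a) == 0L ||
             all(nchar(a) == 1L & a %in% c("A", "C", "G", "T")), logical(1))
  vcf <- vcf[snp, ]
  rr <- rr[snp]
  ref <- ref[snp]; alt <- alt[snp]
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field")
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  alleles <- mapply(function(r, a) c(r, as.character(a)),
                    ref, alt, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  parsed <- parse_gt(gt)
  out <- list()
  for (ctg in unique(contig)) {
    i <- which(contig == ctg)
    i <- i[order(pos[i])]
    dup <- duplicated(pos[i])
    if (any(dup)) {
      warning(sum(dup), " duplicated position(s) on ", ctg,
              "; keeping the first record at each")
      i <- i[!dup]
    }
    out[[ctg]] <- genotype_matrix(
      ctg, pos[i], alleles[i],
      parsed$a1[i, , drop = FALSE], parsed$a2[i, , drop = FALSE], samples)
  }
  out
}

# GT character matrix -> two integer allele-index matrices (1-based, NA miss)
parse_gt <- function(gt) {
  dm <- dim(gt)
  g <- gsub("|", "/", as.character(gt), fixed = TRUE)
  g <- sub(":.*$", "", g)                     # drop any trailing fields
  diplo <- grepl("^[0-9]+/[0-9]+$", g)
  a1 <- rep(NA_integer_, length(g)); a2 <- a1
  a1[diplo] <- as.integer(sub("/.*$", "", g[diplo])) + 1L
  a2[diplo] <- as.integer(sub("^.*/", "", g[diplo])) + 1L
  dim(a1) <- dm; dim(a2) <- dm
  list(a1 = a1, a2 = a2)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a standards-compliant VCF with a contig header line, GT as the only
#' FORMAT field and missing calls as `./.`. Multiallelic sites become one
#' record with comma-separated ALT alleles. An empty matrix yields a valid
#' header-only VCF.
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @param contig_length optional contig length for the header (defaults to
#'   the last site position).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path, contig_length = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(contig_length))
    contig_length <- if (n_sites(G)) max(G$positions) else 1L
  hdr <- c("##fileformat=VCFv4.2",
           "##source=divscan",
           sprintf("##contig=<ID=%s,length=%d>", G$contig,
                   as.integer(contig_length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", G$samples), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n_sites(G) == 0L) return(invisible(path))
  ref <- vapply(G$alleles, `[`, character(1), 1L)
  alt <- vapply(G$alleles, function(a)
    if (length(a) > 1L) paste(a[-1L], collapse = ",") else ".", character(1))
  gt <- matrix(".", n_sites(G), length(G$samples))
  ok <- !is.na(G$a1)
  gt[ok] <- paste0(G$a1[ok] - 1L, "/", G$a2[ok] - 1L)
  gt[!ok] <- "./."
  body <- paste(G$contig, G$positions, ".", ref, alt, ".", ".", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
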
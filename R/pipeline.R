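#' Assemble and validate a pipeline run configuration
#'
#' All analysis parameters default to the study's printed values:
#' per-population genotyping threshold 0.75, 15-kb windows with 5-kb steps,
#' 20% minimum window coverage, 1000 bootstrap replicates at the 95% level,
#' 0.01-cM decay bins under a 1430 cM / 400 Mb recombination model. The
#' configuration is serialized in full into the output directory for
#' provenance.
#'
#' @param vcf path to the genotype VCF.
#' @param samples_tsv path to the sample table (see [read_sample_table()]).
#' @param regions_tsv path to the region table (see [read_region_table()]).
#' @param out_dir output directory, created if needed.
#' @param comparisons `"auto"` to enumerate the full study design from the
#'   sample table, or a list of `list(id =, popA =, popB =)` entries.
#' @param missingness_threshold,window_size,step,min_coverage,n_boot,
#'   ci_level,bin_cM,loess_span,map_length_cM,genome_size_bp analysis
#'   parameters; defaults are the study's.
#' @param seed top-level seed; all stochastic stages derive child seeds.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf, samples_tsv, regions_tsv, out_dir,
                       comparisons = "auto",
                       missingness_threshold = 0.75,
                       window_size = 15000L, step = 5000L,
                       min_coverage = 0.20,
                       n_boot = 1000L, ci_level = 0.95,
                       bin_cM = 0.01, loess_span = 0.3,
                       map_length_cM = 1430, genome_size_bp = 400e6,
                       seed = 1L) {
  cfg <- list(vcf = vcf, samples_tsv = samples_tsv,
              regions_tsv = regions_tsv, out_dir = out_dir,
              comparisons = comparisons,
              missingness_threshold = missingness_threshold,
              window_size = as.integer(window_size), step = as.integer(step),
              min_coverage = min_coverage, n_boot = as.integer(n_boot),
              ci_level = ci_level, bin_cM = bin_cM, loess_span = loess_span,
              map_length_cM = map_length_cM, genome_size_bp = genome_size_bp,
              seed = as.integer(seed))
  stopifnot(cfg$missingness_threshold > 0, cfg$missingness_threshold <= 1,
            cfg$window_size >= cfg$step, cfg$step > 0,
            cfg$min_coverage >= 0, cfg$min_coverage <= 1,
            cfg$n_boot >= 2, cfg$ci_level > 0, cfg$ci_level < 1,
            cfg$bin_cM > 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @return for `read_run_config`, a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$comparisons) && !identical(raw$comparisons, "auto") &&
      is.data.frame(raw$comparisons))
    raw$comparisons <- lapply(seq_len(nrow(raw$comparisons)), function(i)
      list(id = raw$comparisons$id[i],
           popA = unlist(raw$comparisons$popA[i]),
           popB = unlist(raw$comparisons$popB[i])))
  do.call(run_config, raw[setdiff(names(raw), character())])
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

# resolve the configured comparisons into comparison_spec objects
resolve_comparisons <- function(config, samples) {
  if (identical(config$comparisons, "auto"))
    return(enumerate_comparisons(samples))
  specs <- lapply(config$comparisons, function(cmp)
    comparison_spec(cmp$id, "custom",
                    list(list(name = cmp$id, popA = cmp$popA,
                              popB = cmp$popB))))
  names(specs) <- vapply(specs, `[[`, character(1), "comparison_id")
  specs
}

# per-pair site statistics inside one region of one contig matrix
pair_region_stats <- function(G, region, pair, threshold) {
  sub <- subset_region(G, region$start, region$end)
  keep <- filter_pair_missingness(sub, pair$popA, pair$popB, threshold)
  sub <- subset_sites(sub, keep)
  list(components = site_components(sub, pair$popA, pair$popB),
       dxy = site_dxy(sub, pair$popA, pair$popB))
}

#' Run the full divergence-scan pipeline
#'
#' Loads genotypes and metadata, then produces per comparison: a per-site
#' component table, a windowed scan over the color-locus interval, a
#' bootstrap genomic baseline from the unlinked intervals, and a
#' recombination-distance decay table -- plus a provenance copy of the
#' configuration, a run log and a plain-text summary report. Rerunning with
#' the same configuration and seed reproduces every analysis table
#' byte-identically (the log carries wall-clock timestamps).
#'
#' @param config a [run_config()] or path to its JSON serialization.
#' @param stages subset of `c("sites", "windows", "baseline", "decay")`.
#' @return invisibly, a list with the per-comparison results and the paths
#'   of every file written.
#' @export
run_scan <- function(config,
                     stages = c("sites", "windows", "baseline", "decay")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run_log.txt"), "w")
  on.exit(close(logf))
  log_line(logf, "divscan ", as.character(utils::packageVersion("divscan")),
           " | R ", getRversion(), " | seed ", config$seed)

  stage <- "load"
  res <- tryCatch({
    samples <- read_sample_table(config$samples_tsv)
    regions <- read_region_table(config$regions_tsv)
    mats <- read_genotypes(config$vcf, samples$sample_id)
    log_line(logf, "loaded ", sum(vapply(mats, n_sites, integer(1))),
             " SNP sites on ", length(mats), " contig(s), ",
             nrow(samples), " samples")
    specs <- resolve_comparisons(config, samples)
    recomb <- recombination_model(config$map_length_cM, config$genome_size_bp)
    color <- regions[regions$is_color_locus, , drop = FALSE]
    func <- regions[regions$is_functional_65kb, , drop = FALSE]
    unlinked <- regions[regions$is_unlinked, , drop = FALSE]
    paths <- character()
    report <- character()
    out <- list()

    for (si in seq_along(specs)) {
      spec <- specs[[si]]
      id <- spec$comparison_id
      stage <- paste0("sites[", id, "]")
      # per-pair stats per region
      reg_rows <- which(regions$is_color_locus | regions$is_unlinked)
      site_tab <- NULL
      comp_color <- list(); dxy_color <- list()
      comp_unl <- list(); dxy_unl <- list()
      for (p in spec$pairs) {
        pair_dxy_unl <- NULL
        for (ri in reg_rows) {
          region <- regions[ri, ]
          if (!region$contig %in% names(mats)) next
          st <- pair_region_stats(mats[[region$contig]], region, p,
                                  config$missingness_threshold)
          if (region$is_color_locus) {
            comp_color[[length(comp_color) + 1L]] <- st$components
            dxy_color[[length(dxy_color) + 1L]] <- st$dxy
          }
          if (region$is_unlinked) {
            comp_unl[[length(comp_unl) + 1L]] <- st$components
            pair_dxy_unl <- rbind(pair_dxy_unl, st$dxy)
          }
          if ("sites" %in% stages) {
            cmp <- st$components
            den <- cmp$a + cmp$b + cmp$c
            site_tab <- rbind(site_tab, data.frame(
              contig = region$contig, pos = cmp$position,
              comparison_id = p$name, a = cmp$a, num_den = den,
              theta_site = ifelse(!is.na(den) & den != 0, cmp$a / den,
                                  NA_real_),
              dxy_site = st$dxy$dxy,
              n_genotyped_A = cmp$n_A, n_genotyped_B = cmp$n_B))
          }
        }
        # one pooled dxy frame per member pair: groups combine dxy as the
        # mean across comparisons of per-comparison means
        if (!is.null(pair_dxy_unl))
          dxy_unl[[length(dxy_unl) + 1L]] <- pair_dxy_unl
      }
      if ("sites" %in% stages && !is.null(site_tab)) {
        f <- file.path(config$out_dir, paste0("sites_", id, ".tsv"))
        utils::write.table(site_tab, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, f)
        log_line(logf, id, ": ", nrow(site_tab), " site rows")
      }

      if ("windows" %in% stages && length(comp_color) && nrow(color)) {
        stage <- paste0("windows[", id, "]")
        win <- make_windows(color$end[1], config$window_size, config$step,
                            contig = color$contig[1])
        win <- window_estimates(comp_color, dxy_color, win,
                                config$min_coverage)
        bed <- data.frame(contig = win$contig, start0 = win$start - 1L,
                          end = win$end, comparison_id = id,
                          theta = win$theta, dxy_mean = win$dxy_mean,
                          coverage = win$coverage,
                          n_positions = win$n_positions)
        f <- file.path(config$out_dir, paste0("windows_", id, ".tsv"))
        utils::write.table(bed, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, f)
        out[[id]]$windows <- win
      }

      if ("baseline" %in% stages && length(comp_unl)) {
        stage <- paste0("baseline[", id, "]")
        est <- combine_group(comp_unl, dxy_unl, id)
        ci <- bootstrap_ci(comp_unl, "theta", config$n_boot,
                           config$ci_level, child_seed(config$seed, si))
        row <- data.frame(comparison_id = id, region_class = "unlinked",
                          theta = est$theta, ci_lower = ci$lower,
                          ci_upper = ci$upper, dxy_mean = est$dxy_mean,
                          n_positions = est$n_positions,
                          n_reps = config$n_boot, seed = ci$seed)
        out[[id]]$baseline <- row
        report <- c(report, sprintf(
          "%s: unlinked-interval background theta average = %.3f, %d %% CI = %.3f-%.3f (dxy mean = %.4f, %d positions)",
          id, est$theta, round(100 * config$ci_level), ci$lower, ci$upper,
          est$dxy_mean, est$n_positions))
      }

      if ("decay" %in% stages && length(comp_color) && nrow(func)) {
        stage <- paste0("decay[", id, "]")
        comp_all <- do.call(rbind, comp_color)
        dist <- distance_to_locus(comp_all$position, func$start[1],
                                  func$end[1], recomb)
        bins <- bin_decay(comp_all, dist, config$bin_cM)
        # presentational only: tolerate short decay tables quietly
        bins$theta_smoothed <- tryCatch(
          suppressWarnings(
            loess_smooth(bins$cM_mid, bins$theta, config$loess_span)),
          error = function(e) rep(NA_real_, nrow(bins)))
        dec <- data.frame(comparison_id = id, bins)
        f <- file.path(config$out_dir, paste0("decay_", id, ".tsv"))
        utils::write.table(dec, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, f)
        out[[id]]$decay <- dec
      }
    }

    if ("baseline" %in% stages) {
      base_tab <- do.call(rbind, lapply(out, `[[`, "baseline"))
      if (!is.null(base_tab)) {
        f <- file.path(config$out_dir, "baseline.tsv")
        utils::write.table(base_tab, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, f)
      }
    }
    fe <- file.path(config$out_dir, "config_echo.json")
    write_run_config(config, fe)
    fr <- file.path(config$out_dir, "report.txt")
    writeLines(report, fr)
    paths <- c(paths, fe, fr)
    log_line(logf, "done: ", length(paths), " output files")
    list(results = out, paths = paths, report = report)
  }, error = function(e) {
    log_line(logf, "FAILED at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
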
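#' Enumerate the study's comparison design from sample metadata
#'
#' From a sample table covering five hybrid zones, builds the full
#' comparison design used for the divergence scans:
#'
#' * one parapatric comparison per hybrid zone -- four within-species zones
#'   plus the between-species zone (the zone containing the incipient
#'   species, recognised by the `himera` phenotype class);
#' * allopatric groups of race pairs drawn from different within-species
#'   zones, by phenotype: postman vs rayed, postman vs postman, rayed vs
#'   rayed. The two Panamanian postman races (the only case of two
#'   same-phenotype races in one zone) are merged into a single race unit,
#'   and the incipient-species-zone taxa are excluded from all
#'   within-species comparisons.
#'
#' With the study's design -- 4 postman race units and 3 rayed units -- the
#' group sizes are 9 (4 x 3 minus the 3 same-zone parapatric pairs),
#' 6 (postman pairs) and 3 (rayed pairs). Enumeration is a pure function of
#' the metadata: order-independent and deterministic (pairs sorted by name).
#'
#' @param samples data.frame from [read_sample_table()].
#' @return list of `comparison_spec` objects, each a list with
#'   `comparison_id`, `category` and `pairs` (a list of `popA`/`popB`
#'   sample-id pairs; parapatric specs have exactly one pair).
#' @export
enumerate_comparisons <- function(samples) {
  samples <- validate_sample_table(samples)
  ing <- samples[samples$role == "ingroup", , drop = FALSE]
  zones <- sort(unique(ing$hybrid_zone))
  if (length(zones) < 5L)
    stop("expected samples from 5 hybrid zones, found ",
         length(zones), ": ", paste(zones, collapse = ", "))
  between_zone <- unique(ing$hybrid_zone[ing$phenotype_class == "himera"])
  if (length(between_zone) != 1L)
    stop("expected exactly one hybrid zone containing the incipient ",
         "species (phenotype_class 'himera')")

  ids_of <- function(taxa, zone)
    ing$sample_id[ing$taxon %in% taxa & ing$hybrid_zone == zone]

  specs <- list()
  for (z in zones) {
    zs <- ing[ing$hybrid_zone == z, , drop = FALSE]
    taxa <- sort(unique(zs$taxon))
    if (length(taxa) != 2L)
      stop("hybrid zone '", z, "' must hold exactly 2 taxa, found: ",
           paste(taxa, collapse = ", "))
    cat_z <- if (z == between_zone) "parapatric_between_species"
             else "parapatric_within"
    specs[[length(specs) + 1L]] <- comparison_spec(
      paste0("parapatric_", z), cat_z,
      list(list(name = paste(taxa, collapse = "_vs_"),
                popA = ids_of(taxa[1], z), popB = ids_of(taxa[2], z))))
  }

  # allopatric race units: within-species zones only, Panama-style
  # same-phenotype zone pairs merged into one unit
  within <- ing[ing$hybrid_zone != between_zone, , drop = FALSE]
  units <- unique(within[, c("taxon", "hybrid_zone", "phenotype_class")])
  merged <- list()
  for (z in unique(units$hybrid_zone)) {
    uz <- units[units$hybrid_zone == z, , drop = FALSE]
    for (ph in unique(uz$phenotype_class)) {
      up <- uz[uz$phenotype_class == ph, , drop = FALSE]
      nm <- if (nrow(up) > 1L) paste0(z, "_", ph)
            else paste0(up$taxon, "@", z)
      merged[[length(merged) + 1L]] <- list(
        name = nm, zone = z, phenotype = ph,
        ids = ing$sample_id[ing$hybrid_zone == z &
                            ing$taxon %in% up$taxon])
    }
  }
  nm <- vapply(merged, `[[`, character(1), "name")
  merged <- merged[order(nm)]
  ph <- vapply(merged, `[[`, character(1), "phenotype")
  zn <- vapply(merged, `[[`, character(1), "zone")
  pm <- which(ph == "postman"); ry <- which(ph == "rayed")

  pair_list <- function(ii, jj, exclude_same_zone) {
    out <- list()
    for (i in ii) for (j in jj) {
      if (i >= j && identical(ii, jj)) next
      if (exclude_same_zone && zn[i] == zn[j]) next
      out[[length(out) + 1L]] <- list(
        name = paste0(merged[[i]]$name, "_vs_", merged[[j]]$name),
        popA = merged[[i]]$ids, popB = merged[[j]]$ids)
    }
    out
  }
  specs[[length(specs) + 1L]] <- comparison_spec(
    "allopatric_postman_rayed", "allopatric_postman_rayed",
    pair_list(pm, ry, exclude_same_zone = TRUE))
  specs[[length(specs) + 1L]] <- comparison_spec(
    "allopatric_postman_postman", "allopatric_postman_postman",
    pair_list(pm, pm, exclude_same_zone = TRUE))
  specs[[length(specs) + 1L]] <- comparison_spec(
    "allopatric_rayed_rayed", "allopatric_rayed_rayed",
    pair_list(ry, ry, exclude_same_zone = TRUE))
  names(specs) <- vapply(specs, `[[`, character(1), "comparison_id")
  specs
}

comparison_spec <- function(id, category, pairs) {
  structure(list(comparison_id = id, category = category, pairs = pairs),
            class = "comparison_spec")
}

#' @export
print.comparison_spec <- function(x, ...) {
  cat(sprintf("%s [%s]: %d pair(s)\n", x$comparison_id, x$category,
              length(x$pairs)))
  for (p in x$pairs)
    cat(sprintf("  %s (%d vs %d samples)\n", p$name,
                length(p$popA), length(p$popB)))
  invisible(x)
}
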
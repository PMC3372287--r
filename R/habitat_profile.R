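#' Percentage of a taxon's records carrying a descriptor
#'
#' The habitat-coverage view: what share of all database records for one taxon
#' is associated with a given descriptor. Percentages across descriptors may
#' sum past 100 because descriptors overlap on records.
#'
#' @param m A `count_matrix`.
#' @param taxon Taxon row name.
#' @param d Descriptor label.
#' @return A percentage in `[0, 100]`.
#' @export
habitat_percent <- function(m, taxon, d) {
  stopifnot(inherits(m, "count_matrix"))
  if (!taxon %in% rownames(m$counts)) stop("unknown taxon: ", taxon, call. = FALSE)
  d <- check_descriptor(m, d)
  N <- m$baseline[[taxon]]
  if (N == 0) {
    stop("taxon '", taxon, "' has no baseline records: habitat percent undefined",
         call. = FALSE)
  }
  100 * m$counts[taxon, d] / N
}

#' Habitat preference profile of one taxon
#'
#' Ranks every descriptor with at least one record for the taxon by the share
#' of the taxon's total records it captures (decreasing; ties broken by label),
#' and classifies the taxon as cosmopolitan when it is linked to at least
#' `threshold` of the vocabulary's descriptors. "Linked" means having at least
#' `min_count` records under the descriptor (default 1 — any record counts).
#'
#' @param m A `count_matrix`.
#' @param taxon Taxon row name.
#' @param threshold Cosmopolitanism coverage threshold as a fraction of all
#'   descriptors (default 0.90).
#' @param min_count Minimum records for a descriptor to count as linked
#'   (default 1).
#' @return An object of class `habitat_profile`: `taxon`, `entries` (data.frame
#'   `descriptor`, `h` sorted by decreasing `h`), `n_descriptors`,
#'   `coverage_fraction`, `cosmopolitan`.
#' @export
build_profile <- function(m, taxon, threshold = 0.90, min_count = 1) {
  stopifnot(inherits(m, "count_matrix"))
  descs <- descriptor_labels(m)
  h <- vapply(descs, function(d) habitat_percent(m, taxon, d), numeric(1))
  n <- m$counts[taxon, descs]
  linked <- n >= min_count
  keep <- h > 0
  ord <- order(-h[keep], descs[keep])
  entries <- data.frame(descriptor = descs[keep][ord], h = unname(h[keep][ord]),
                        stringsAsFactors = FALSE)
  coverage <- sum(linked) / length(descs)
  structure(
    list(taxon = taxon, entries = entries, n_descriptors = length(descs),
         coverage_fraction = coverage,
         cosmopolitan = coverage >= threshold),
    class = "habitat_profile"
  )
}

#' @export
print.habitat_profile <- function(x, ...) {
  cat("<habitat_profile> ", x$taxon, ": linked to ",
      round(100 * x$coverage_fraction, 1), "% of descriptors (",
      if (x$cosmopolitan) "cosmopolitan" else "specific", ")\n", sep = "")
  if (nrow(x$entries)) {
    top <- utils::head(x$entries, 5)
    cat(paste0("  ", top$descriptor, ": ", round(top$h, 2), "%\n"), sep = "")
  }
  invisible(x)
}

#' Habitat profiles for every analysis taxon
#'
#' @param m A `count_matrix`.
#' @inheritParams build_profile
#' @return Named list of `habitat_profile` objects over the analysis taxa.
#' @export
build_profiles <- function(m, threshold = 0.90, min_count = 1) {
  stopifnot(inherits(m, "count_matrix"))
  taxa <- m$analysis[m$baseline[m$analysis] > 0]
  stats::setNames(
    lapply(taxa, build_profile, m = m, threshold = threshold,
           min_count = min_count),
    taxa
  )
}

#' Census of cosmopolitan taxa
#'
#' @param profiles List of `habitat_profile` objects.
#' @return List with `count` (cosmopolitan profiles), `total`, and `percent`
#'   (share of profiles classified cosmopolitan, in percent).
#' @export
cosmopolitan_census <- function(profiles) {
  stopifnot(length(profiles) > 0)
  cos <- vapply(profiles, `[[`, logical(1), "cosmopolitan")
  list(count = sum(cos), total = length(cos),
       percent = 100 * sum(cos) / length(cos))
}

#' Write habitat profiles as TSV
#'
#' Long format (`taxon`, `rank`, `descriptor`, `h_percent`) plus an optional
#' census table (`taxon`, `coverage_fraction`, `cosmopolitan`).
#'
#' @param profiles List of `habitat_profile` objects.
#' @param path Long-format TSV path.
#' @param census_path Optional census TSV path.
#' @param digits Rounding for reported percentages (default 2).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, census_path = NULL, digits = 2) {
  long <- do.call(rbind, lapply(profiles, function(p) {
    if (!nrow(p$entries)) return(NULL)
    data.frame(taxon = p$taxon, rank = seq_len(nrow(p$entries)),
               descriptor = p$entries$descriptor,
               h_percent = round(p$entries$h, digits),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(census_path)) {
    census <- data.frame(
      taxon = vapply(profiles, `[[`, character(1), "taxon"),
      coverage_fraction = round(
        vapply(profiles, `[[`, numeric(1), "coverage_fraction"), 4),
      cosmopolitan = vapply(profiles, `[[`, logical(1), "cosmopolitan"),
      stringsAsFactors = FALSE
    )
    utils::write.table(census, census_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
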
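#' Construct a community composition
#'
#' A labelled vector of percentage proportions, as read off a phylum-level bar
#' chart or a reference survey table. Proportions sum to 100 over the included
#' taxa before any frequency filtering.
#'
#' @param labels Taxon names.
#' @param props Percentage proportions (non-negative).
#' @return An object of class `composition`.
#' @export
composition <- function(labels, props) {
  stopifnot(length(labels) == length(props))
  props <- as.numeric(props)
  if (any(props < 0)) stop("proportions must be non-negative", call. = FALSE)
  structure(list(labels = as.character(labels), props = props),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition> ", length(x$labels), " taxa\n", sep = "")
  if (length(x$labels)) {
    cat(paste0("  ", x$labels, ": ", round(x$props, 2), "%\n"), sep = "")
  }
  invisible(x)
}

#' Subcommunity composition of one or more descriptors
#'
#' For a single descriptor this is the subcommunity percentage vector as a
#' `composition`. For several descriptors the per-taxon counts are summed
#' before forming proportions — the offline approximation to a merged Boolean
#' query (records matching more than one of the merged descriptors are counted
#' once per descriptor; true deduplication needs the live database).
#'
#' @param m A `count_matrix`.
#' @param d Descriptor label(s).
#' @return A `composition` over the analysis taxa.
#' @export
subcommunity_composition <- function(m, d) {
  stopifnot(inherits(m, "count_matrix"))
  d <- vapply(d, check_descriptor, character(1), m = m)
  n <- rowSums(m$counts[m$analysis, d, drop = FALSE])
  total <- sum(n)
  if (total == 0) stop("empty subcommunity for: ", paste(d, collapse = ", "),
                       call. = FALSE)
  composition(names(n), 100 * n / total)
}

#' Read a reference composition from TSV
#'
#' Two columns: `taxon`, `percent`.
#'
#' @param path Input TSV.
#' @return A `composition`.
#' @export
read_composition <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "percent") %in% names(tab))) {
    stop("composition TSV needs 'taxon' and 'percent' columns: ", path,
         call. = FALSE)
  }
  composition(tab$taxon, tab$percent)
}

#' Retain the major taxa of a composition
#'
#' Keeps taxa with proportion strictly above `threshold` percent (the
#' bar-chart convention for displaying phyla "found at frequencies higher than
#' 1%"). Proportions are deliberately not renormalized. An empty result is a
#' valid composition, not an error.
#'
#' @param c A `composition`.
#' @param threshold Percent cutoff (default 1).
#' @return A filtered `composition`.
#' @export
filter_major <- function(c, threshold = 1.0) {
  stopifnot(inherits(c, "composition"))
  keep <- c$props > threshold
  composition(c$labels[keep], c$props[keep])
}

#' Compare two compositions
#'
#' Aligns the two compositions on the union of their taxa (missing taxa as 0),
#' tabulates per-taxon differences, and scores the overall mismatch with the
#' Bray-Curtis dissimilarity `sum(|a - b|) / sum(a + b)` — 0 for identical
#' compositions, 1 for fully disjoint ones. Both inputs should have been
#' filtered at the same threshold.
#'
#' @param a,b `composition` objects.
#' @return A list: `table` (data.frame `taxon`, `prop_a`, `prop_b`,
#'   `difference`) and `bray_curtis`. Comparing two empty compositions gives
#'   `bray_curtis = NA` (undefined).
#' @export
compare_compositions <- function(a, b) {
  stopifnot(inherits(a, "composition"), inherits(b, "composition"))
  taxa <- sort(union(a$labels, b$labels))
  pa <- stats::setNames(rep(0, length(taxa)), taxa)
  pb <- pa
  pa[a$labels] <- a$props
  pb[b$labels] <- b$props
  tab <- data.frame(taxon = taxa, prop_a = unname(pa), prop_b = unname(pb),
                    difference = unname(pa - pb), stringsAsFactors = FALSE)
  denom <- sum(pa + pb)
  bc <- if (denom == 0) NA_real_ else sum(abs(pa - pb)) / denom
  list(table = tab, bray_curtis = bc)
}

#' Grouped bar chart of a composition comparison
#'
#' Optional visual check in the style of phylum-level community comparisons.
#'
#' @param cmp Output of [compare_compositions()].
#' @param names_a,names_b Legend labels for the two compositions.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_comparison <- function(cmp, names_a = "query-derived",
                            names_b = "reference", ...) {
  h <- rbind(cmp$table$prop_a, cmp$table$prop_b)
  graphics::barplot(h, beside = TRUE, names.arg = cmp$table$taxon,
                    legend.text = c(names_a, names_b), las = 2,
                    ylab = "percent of community", ...)
}
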
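#' Baseline percentage composition of the analysis taxa
#'
#' The percentage proportions at which the taxa occur in the whole database,
#' unassociated with any keyword — the "global database metacommunity" that
#' serves as the reference for every enrichment comparison.
#'
#' @param m A `count_matrix`.
#' @return Named vector of percentages over the analysis taxa; sums to 100.
#' @export
baseline_percentages <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  total <- bacterial_sum(m)
  if (total == 0) stop("baseline sum is zero: undefined community", call. = FALSE)
  100 * m$baseline[m$analysis] / total
}

#' Percentage composition of a descriptor's subcommunity
#'
#' Each taxon's share of the records matching one descriptor, computed over the
#' analysis taxa. An empty column (no records under the descriptor at all)
#' yields `NA` for every taxon — the subcommunity is undefined, not uniform.
#'
#' @param m A `count_matrix`.
#' @param d Descriptor label.
#' @return Named vector of percentages over the analysis taxa; sums to 100
#'   when the column is non-empty.
#' @export
subcommunity_percentages <- function(m, d) {
  stopifnot(inherits(m, "count_matrix"))
  d <- check_descriptor(m, d)
  total <- bacterial_sum(m, d)
  n <- m$counts[m$analysis, d]
  if (total == 0) return(stats::setNames(rep(NA_real_, length(n)), names(n)))
  100 * n / total
}

#' Net percentage variation over the baseline
#'
#' Subcommunity percentage minus baseline percentage, in signed percentage
#' points. Exposed on the percentage pair (not only inside
#' [enrichment_table()]) so published percentage values can be compared
#' directly.
#'
#' @param p_sub,p_base Percentages.
#' @return `p_sub - p_base`.
#' @examples
#' net_variation(20.81, 11.78) # +9.03
#' @export
net_variation <- function(p_sub, p_base) p_sub - p_base

#' Fold change over the baseline percentage
#'
#' @param p_sub,p_base Percentages. `p_base = 0` gives `NA` (undefined fold).
#' @return `p_sub / p_base`.
#' @export
fold_change <- function(p_sub, p_base) {
  ifelse(p_base == 0, NA_real_, p_sub / p_base)
}

#' Enrichment/depletion table relative to the global baseline
#'
#' For every (analysis taxon, descriptor) pair: the taxon's baseline percentage
#' `p_base`, its percentage within the descriptor's subcommunity `p_sub`, the
#' net variation `p_sub - p_base` (percentage points) and the fold change
#' `p_sub / p_base`. Each descriptor column is computed independently of all
#' others (each is closed under its own column total), so adding or removing
#' descriptors never changes existing cells.
#'
#' Status semantics: `absent` when the pair has zero records (net and fold are
#' then `NA`, the blank-cell convention); otherwise `enriched`, `depleted` or
#' `unchanged` by the sign of the net variation at full precision. Display
#' banding by intensity is a reporting concern, not encoded here.
#'
#' @param m A `count_matrix`.
#' @param descriptors Labels to include (default all).
#' @return A long data.frame: `taxon`, `descriptor`, `n`, `p_base`, `p_sub`,
#'   `net`, `fold`, `status`.
#' @export
enrichment_table <- function(m, descriptors = descriptor_labels(m)) {
  stopifnot(inherits(m, "count_matrix"))
  p_base <- baseline_percentages(m)
  out <- lapply(descriptors, function(d) {
    d <- check_descriptor(m, d)
    p_sub <- subcommunity_percentages(m, d)
    n <- m$counts[m$analysis, d]
    net <- net_variation(p_sub, p_base)
    fold <- fold_change(p_sub, p_base)
    status <- ifelse(n == 0, "absent",
              ifelse(is.na(net), "absent",
              ifelse(net > 0, "enriched",
              ifelse(net < 0, "depleted", "unchanged"))))
    net[n == 0] <- NA_real_
    fold[n == 0] <- NA_real_
    data.frame(taxon = names(p_base), descriptor = d, n = unname(n),
               p_base = unname(p_base), p_sub = unname(p_sub),
               net = unname(net), fold = unname(fold),
               status = unname(status), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write enrichment results as TSV
#'
#' Writes the tidy long table, and optionally a wide layout with paired rows
#' per taxon (upper row: net variation; lower row: fold change), both rounded
#' half-even to `digits` decimals. Absent cells are written blank.
#'
#' @param et Output of [enrichment_table()].
#' @param path Long-format TSV path.
#' @param wide_path Optional paired-row wide TSV path.
#' @param digits Rounding for reported values (default 2).
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(et, path, wide_path = NULL, digits = 2) {
  long <- et
  num <- c("p_base", "p_sub", "net", "fold")
  long[num] <- lapply(long[num], round, digits = digits)
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  if (!is.null(wide_path)) {
    taxa <- unique(et$taxon)
    descs <- unique(et$descriptor)
    get <- function(field) {
      sapply(descs, function(d) {
        v <- et[[field]][match(paste(taxa, d), paste(et$taxon, et$descriptor))]
        round(v, digits)
      })
    }
    net <- matrix(get("net"), nrow = length(taxa))
    fold <- matrix(get("fold"), nrow = length(taxa))
    rows <- lapply(seq_along(taxa), function(i) {
      rbind(c(taxa[i], "net", net[i, ]), c("", "fold", fold[i, ]))
    })
    wide <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    colnames(wide) <- c("taxon", "value", descs)
    utils::write.table(wide, wide_path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "")
  }
  invisible(path)
}
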
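#' Construct a taxa-by-descriptor count matrix
#'
#' The central container: one row per taxon query unit, one column per
#' descriptor, holding the number of database records matching both, plus the
#' unrestricted baseline count per taxon (the "GenBank" column — records of
#' that taxon with no descriptor applied). Special rows (the Archaea
#' superkingdom, the "uncultured" pseudo-taxon, the Proteobacteria umbrella)
#' are carried for the ratio columns but excluded from the analysis-taxon sums.
#'
#' @param counts Non-negative integer matrix; rownames are taxon names,
#'   colnames descriptor labels.
#' @param baseline Non-negative integer vector, one per taxon (the
#'   descriptor-free total); names must match `rownames(counts)`.
#' @param analysis Character vector of rows to treat as analysis taxa. Defaults
#'   to every row except `archaea`, `uncultured` and `"Proteobacteria"` (the
#'   umbrella would double-count its classes).
#' @param archaea,uncultured Row names of the special taxa, or `NA` if absent.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, baseline, analysis = NULL,
                         archaea = "Archaea", uncultured = "uncultured") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have taxon rownames and descriptor colnames", call. = FALSE)
  }
  if (is.null(names(baseline))) names(baseline) <- rownames(counts)
  baseline <- baseline[rownames(counts)]
  check_counts <- function(x, what) {
    if (anyNA(x) || any(x < 0) || any(x != round(x))) {
      stop(what, " must be non-negative integers", call. = FALSE)
    }
  }
  check_counts(counts, "counts")
  check_counts(baseline, "baseline")
  storage.mode(counts) <- "double"      # uniform storage so TSV IO round-trips
  baseline <- stats::setNames(as.numeric(baseline), names(baseline))
  over <- which(counts > baseline[rownames(counts)], arr.ind = TRUE)
  if (nrow(over)) {
    stop("count exceeds taxon baseline for (",
         rownames(counts)[over[1, 1]], ", ", colnames(counts)[over[1, 2]],
         "): a descriptor-restricted query cannot exceed the unrestricted one",
         call. = FALSE)
  }
  if (!archaea %in% rownames(counts)) archaea <- NA_character_
  if (!uncultured %in% rownames(counts)) uncultured <- NA_character_
  if (is.null(analysis)) {
    analysis <- setdiff(rownames(counts),
                        c(archaea, uncultured, "Proteobacteria"))
  }
  stopifnot(all(analysis %in% rownames(counts)))
  structure(
    list(counts = counts, baseline = baseline, analysis = analysis,
         archaea = archaea, uncultured = uncultured),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " taxa (", length(x$analysis),
      " analysis units) x ", ncol(x$counts), " descriptors\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Descriptor labels of a count matrix
#' @param m A `count_matrix`.
#' @return Character vector of descriptor labels (column order).
#' @export
descriptor_labels <- function(m) colnames(m$counts)

check_descriptor <- function(m, d) {
  if (!d %in% colnames(m$counts)) {
    stop("unknown descriptor: ", d, call. = FALSE)
  }
  d
}

#' Sum of counts over the analysis taxa
#'
#' The bacterial sum: total records over the 29 analysis units (phyla and
#' proteobacterial classes), excluding Archaea, the Proteobacteria umbrella and
#' pseudo-taxa. With `d = NULL` it is the baseline sum — the denominator of the
#' global-database ("metacommunity") percentages.
#'
#' @param m A `count_matrix`.
#' @param d Descriptor label, or `NULL` for the baseline.
#' @return A single number.
#' @export
bacterial_sum <- function(m, d = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(d)) {
    sum(m$baseline[m$analysis])
  } else {
    sum(m$counts[m$analysis, check_descriptor(m, d)])
  }
}

#' Ratio of bacterial to archaeal record counts
#'
#' The differential rate at which Bacteria and Archaea occur under a
#' descriptor (or in the whole database with `d = NULL`). When no archaeal
#' records exist the ratio is undefined and `NA` is returned rather than `Inf`,
#' mirroring "absence of sequences" in the source tables.
#'
#' @inheritParams bacterial_sum
#' @return A single number, or `NA` when the archaeal count is zero.
#' @export
bacteria_over_archaea <- function(m, d = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.na(m$archaea)) stop("no Archaea row in this matrix", call. = FALSE)
  arch <- if (is.null(d)) m$baseline[[m$archaea]]
          else m$counts[m$archaea, check_descriptor(m, d)]
  if (arch == 0) return(NA_real_)
  bacterial_sum(m, d) / arch
}

#' Ratio of "uncultured"-labelled records to the bacterial sum
#'
#' How many records carry the "uncultured" description label relative to the
#' records classified at phylum/class level, per descriptor or for the whole
#' database (`d = NULL`).
#'
#' @inheritParams bacterial_sum
#' @return A single number, or `NA` when the bacterial sum is zero.
#' @export
uncultured_ratio <- function(m, d = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.na(m$uncultured)) stop("no uncultured row in this matrix", call. = FALSE)
  bact <- bacterial_sum(m, d)
  if (bact == 0) return(NA_real_)
  unc <- if (is.null(d)) m$baseline[[m$uncultured]]
         else m$counts[m$uncultured, check_descriptor(m, d)]
  unc / bact
}

#' Assemble a count matrix from a vocabulary and a count source
#'
#' Runs one query per taxon (the baseline) and one per (taxon, descriptor)
#' pair, and collects the counts. A missing count is a hard error carrying the
#' offending query text — zero is a legitimate count, absence of an answer is
#' not.
#'
#' @param vocab A `vocabulary`.
#' @param source A count source (see [mock_source()], [cache_source()],
#'   [live_source()]).
#' @param exclude_genome Append `NOT genome` to every query? Default `TRUE`.
#' @return A `count_matrix`.
#' @export
assemble_matrix <- function(vocab, source, exclude_genome = TRUE) {
  stopifnot(inherits(vocab, "vocabulary"))
  taxa <- vocab$taxa
  descs <- vocab$descriptors
  get <- function(d, t) {
    fetch_count(build_query(d, t, exclude_genome = exclude_genome), source)$count
  }
  baseline <- vapply(taxa, function(t) get(NULL, t), numeric(1))
  counts <- vapply(descs, function(d) {
    vapply(taxa, function(t) get(d, t), numeric(1))
  }, numeric(length(taxa)))
  counts <- matrix(counts, nrow = length(taxa),
                   dimnames = list(names(taxa), names(descs)))
  arch <- names(taxa)[vapply(taxa, function(t) t$rank == "superkingdom" &&
                               t$name == "Archaea", logical(1))]
  unc <- names(taxa)[vapply(taxa, function(t) t$rank == "pseudo", logical(1))]
  count_matrix(counts, baseline,
               analysis = intersect(analysis_taxa(vocab), names(taxa)),
               archaea = if (length(arch)) arch[1] else "Archaea",
               uncultured = if (length(unc)) unc[1] else "uncultured")
}

# ---- snapshot TSV dialect ---------------------------------------------------

#' Write a count matrix as a snapshot TSV
#'
#' Layout: taxa as rows; columns `taxon`, `role` (analysis/archaea/uncultured/
#' other), `GenBank` (the baseline), then one column per descriptor.
#'
#' @param m A `count_matrix`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  role <- rep("other", nrow(m$counts))
  names(role) <- rownames(m$counts)
  role[m$analysis] <- "analysis"
  if (!is.na(m$archaea)) role[m$archaea] <- "archaea"
  if (!is.na(m$uncultured)) role[m$uncultured] <- "uncultured"
  tab <- data.frame(taxon = rownames(m$counts), role = role,
                    GenBank = m$baseline, m$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a count matrix from a snapshot TSV
#'
#' Accepts the dialect written by [write_count_matrix()]; a file without the
#' `role` column is accepted, with roles inferred from the reserved names
#' `Archaea`, `uncultured` and `Proteobacteria`. Trailing derived columns
#' (named in `ignore`) are dropped.
#'
#' @param path Snapshot TSV.
#' @param ignore Column names to drop as derived (default `"SUM"` and the two
#'   ratio columns).
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(path,
                              ignore = c("SUM", "Bacteria/Archaea",
                                         "Uncultured/Bacteria")) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("taxon", "GenBank") %in% names(tab))) {
    stop("snapshot TSV needs 'taxon' and 'GenBank' columns: ", path,
         call. = FALSE)
  }
  role <- if ("role" %in% names(tab)) tab$role else rep(NA_character_, nrow(tab))
  keep <- setdiff(names(tab), c("taxon", "role", "GenBank", ignore))
  counts <- as.matrix(tab[, keep, drop = FALSE])
  rownames(counts) <- tab$taxon
  analysis <- if (all(is.na(role))) NULL else tab$taxon[role == "analysis"]
  pick <- function(r, fallback) {
    hit <- tab$taxon[which(role == r)]
    if (length(hit)) hit[1] else fallback
  }
  count_matrix(counts, stats::setNames(tab$GenBank, tab$taxon),
               analysis = analysis,
               archaea = pick("archaea", "Archaea"),
               uncultured = pick("uncultured", "uncultured"))
}
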
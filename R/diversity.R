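#' Diversity and evenness indices of one descriptor subcommunity
#'
#' Treats the records matching one descriptor as a virtual community at
#' phylum/class resolution (the analysis taxa) and computes, with
#' `p_i = n_i / sum(n)` over taxa with `n_i > 0`:
#'
#' * richness `S` (analysis taxa with records),
#' * Simpson concentration `D = sum(p_i^2)` and the inverse Simpson `1/D`
#'   (Hill's N2, the effective number of equally-abundant taxa),
#' * Shannon-Wiener `H' = -sum(p_i log(p_i))`,
#' * Simpson evenness `E1/D = (1/D)/S`,
#' * Pielou evenness `J' = H'/log(S)` (undefined at `S = 1`).
#'
#' The natural logarithm is the default; the published convention does not fix
#' a base, so `log2`/`log10` are available. The log base rescales `H'` only —
#' `J'` is base-invariant.
#'
#' @param m A `count_matrix`.
#' @param d Descriptor label.
#' @param log_base One of `"ln"`, `"log2"`, `"log10"`.
#' @return A `community_indices` list: `descriptor`, `S`, `inv_simpson`,
#'   `shannon`, `simpson_evenness`, `pielou`. An empty column returns `S = 0`
#'   with all indices `NA` (empty-community marker); `S = 1` gives
#'   `inv_simpson = 1`, `shannon = 0` and `pielou = NA`.
#' @examples
#' m <- count_matrix(matrix(c(50, 30, 20), 3, 1,
#'                          dimnames = list(c("A", "B", "C"), "Soil")),
#'                   baseline = c(100, 100, 100))
#' community_indices(m, "Soil")
#' @export
community_indices <- function(m, d, log_base = c("ln", "log2", "log10")) {
  stopifnot(inherits(m, "count_matrix"))
  d <- check_descriptor(m, d)
  log_base <- match.arg(log_base)
  lg <- switch(log_base, ln = log, log2 = log2, log10 = log10)
  n <- m$counts[m$analysis, d]
  n <- n[n > 0]
  S <- length(n)
  if (S == 0) {
    idx <- list(descriptor = d, S = 0L, inv_simpson = NA_real_,
                shannon = NA_real_, simpson_evenness = NA_real_,
                pielou = NA_real_)
    return(structure(idx, class = "community_indices"))
  }
  p <- n / sum(n)
  D <- sum(p^2)
  H <- -sum(p * lg(p))                        # 0*log(0) never arises: p > 0
  structure(
    list(descriptor = d, S = S, inv_simpson = 1 / D, shannon = H,
         simpson_evenness = (1 / D) / S,
         pielou = if (S == 1) NA_real_ else H / lg(S)),
    class = "community_indices"
  )
}

#' @export
print.community_indices <- function(x, ...) {
  cat("<community_indices> ", x$descriptor, ": S=", x$S,
      "  1/D=", round(x$inv_simpson, 4), "  H'=", round(x$shannon, 4),
      "  E1/D=", round(x$simpson_evenness, 4),
      "  J'=", round(x$pielou, 4), "\n", sep = "")
  invisible(x)
}

#' Diversity report over all descriptors
#'
#' One row of indices per descriptor subcommunity, optionally sorted by any
#' index (decreasing, stable, ties broken by descriptor label).
#'
#' @param m A `count_matrix`.
#' @param sort_by `NULL` (input order) or one of `"S"`, `"inv_simpson"`,
#'   `"shannon"`, `"simpson_evenness"`, `"pielou"`.
#' @inheritParams community_indices
#' @return A data.frame with columns `descriptor`, `S`, `inv_simpson`,
#'   `shannon`, `simpson_evenness`, `pielou`.
#' @export
index_report <- function(m, sort_by = NULL, log_base = "ln") {
  stopifnot(inherits(m, "count_matrix"))
  rows <- lapply(descriptor_labels(m), function(d) {
    as.data.frame(unclass(community_indices(m, d, log_base)),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(sort_by)) {
    stopifnot(sort_by %in% c("S", "inv_simpson", "shannon",
                             "simpson_evenness", "pielou"))
    out <- out[order(-out[[sort_by]], out$descriptor), ]
    rownames(out) <- NULL
  }
  out
}

#' Write a diversity report as TSV
#'
#' @param report Output of [index_report()].
#' @param path Output TSV.
#' @param digits Rounding for reported indices (default 4).
#' @return `path`, invisibly.
#' @export
write_index_report <- function(report, path, digits = 4) {
  num <- c("inv_simpson", "shannon", "simpson_evenness", "pielou")
  report[num] <- lapply(report[num], round, digits = digits)
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
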
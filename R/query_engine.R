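#' Build a Boolean record-count query
#'
#' Assembles the query grammar used throughout: the descriptor's synonym
#' clause, joined by `AND` to the taxon clause, with `NOT genome` appended to
#' exclude records from genome sequencing projects. Taxa with a real rank are
#' restricted to the `[Organism]` field so that a phylum mentioned elsewhere in
#' an unrelated record does not count; pseudo-taxa (e.g. "uncultured") are
#' searched as bare free text, since that label lives in the record description
#' rather than the organism field.
#'
#' @param descriptor A `descriptor`, or `NULL` for an unrestricted (baseline)
#'   taxon query.
#' @param taxon A `taxon_query`, or `NULL` for a descriptor-only query.
#' @param exclude_genome Append `NOT genome`? Default `TRUE`.
#' @return The query as a single string.
#' @examples
#' build_query(descriptor("Alkaline", c("Alkaline", "alkaliphilic")),
#'             taxon_query("Actinobacteria", "phylum"))
#' # "(Alkaline OR alkaliphilic) AND Actinobacteria[Organism] NOT genome"
#' @export
build_query <- function(descriptor = NULL, taxon = NULL, exclude_genome = TRUE) {
  if (is.null(descriptor) && is.null(taxon)) {
    stop("at least one of descriptor/taxon must be given", call. = FALSE)
  }
  parts <- character()
  if (!is.null(descriptor)) {
    stopifnot(inherits(descriptor, "descriptor"))
    parts <- expand_descriptor(descriptor)
  }
  if (!is.null(taxon)) {
    stopifnot(inherits(taxon, "taxon_query"))
    taxon_clause <- if (taxon$rank == "pseudo") {
      taxon$name
    } else {
      paste0(taxon$organism_term, "[Organism]")
    }
    parts <- c(parts, taxon_clause)
  }
  q <- paste(parts, collapse = " AND ")
  if (exclude_genome) q <- paste(q, "NOT genome")
  q
}

#' Fetch the record count for a query from a count source
#'
#' @param query Query string (see [build_query()]).
#' @param source A count source created by [mock_source()], [cache_source()] or
#'   [live_source()].
#' @return A `count_result` list: `query_text`, `count` (non-negative integer),
#'   `retrieved_at` (POSIXct), `source` (`"mock"`, `"cache"` or `"live"`).
#' @export
fetch_count <- function(query, source) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query))
  UseMethod("fetch_count", source)
}

new_count_result <- function(query, count, source) {
  count <- as.numeric(count)
  if (is.na(count) || count < 0) {
    stop("count source returned an invalid count for query: ", query, call. = FALSE)
  }
  structure(
    list(query_text = query, count = count, retrieved_at = Sys.time(),
         source = source),
    class = "count_result"
  )
}

#' @export
print.count_result <- function(x, ...) {
  cat("<count_result> ", x$count, "  [", x$source, "]  ", x$query_text, "\n",
      sep = "")
  invisible(x)
}

# ---- mock source ------------------------------------------------------------

#' Mock count source primed with fixed counts
#'
#' @param counts Named numeric vector or list mapping query text to count.
#' @param default Count returned for unprimed queries; `NA` (the default) makes
#'   an unprimed query a hard error rather than a silent zero.
#' @return A count source.
#' @examples
#' src <- mock_source(c("Actinobacteria[Organism] NOT genome" = 157719))
#' fetch_count("Actinobacteria[Organism] NOT genome", src)$count
#' @export
mock_source <- function(counts = list(), default = NA) {
  structure(
    list(counts = as.list(counts), default = default),
    class = c("mock_source", "count_source")
  )
}

#' @export
fetch_count.mock_source <- function(query, source) {
  n <- source$counts[[query]]
  if (is.null(n)) n <- source$default
  if (is.na(n)) {
    stop("missing count (mock source not primed) for query: ", query,
         call. = FALSE)
  }
  new_count_result(query, n, "mock")
}

# ---- cache source -----------------------------------------------------------

#' On-disk cached count source
#'
#' The cache is a TSV with columns `query`, `count`, `date`, making a
#' database-mining run a dated, citable snapshot. In cache-only mode
#' (`upstream = NULL`) a miss is a hard error, never a silent zero. With an
#' upstream source, misses are fetched once and written through; repeated
#' fetches of the same query hit the cache.
#'
#' @param path Cache TSV file; created on first write-through.
#' @param upstream Optional fallback count source for misses.
#' @return A count source.
#' @export
cache_source <- function(path, upstream = NULL) {
  env <- new.env(parent = emptyenv())
  env$table <- read_count_cache(path)
  env$upstream_calls <- 0L
  structure(
    list(path = path, upstream = upstream, env = env),
    class = c("cache_source", "count_source")
  )
}

read_count_cache <- function(path) {
  if (!file.exists(path)) {
    return(data.frame(query = character(), count = numeric(),
                      date = character(), stringsAsFactors = FALSE))
  }
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE) |>
    transform(count = as.numeric(count))
}

#' @export
fetch_count.cache_source <- function(query, source) {
  tab <- source$env$table
  hit <- match(query, tab$query)
  if (!is.na(hit)) {
    return(new_count_result(query, tab$count[hit], "cache"))
  }
  if (is.null(source$upstream)) {
    stop("missing count in cache (", source$path, ") for query: ", query,
         call. = FALSE)
  }
  res <- fetch_count(query, source$upstream)
  source$env$upstream_calls <- source$env$upstream_calls + 1L
  row <- data.frame(query = query, count = res$count,
                    date = format(Sys.Date()), stringsAsFactors = FALSE)
  source$env$table <- rbind(tab, row)
  utils::write.table(source$env$table, source$path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  new_count_result(query, res$count, "cache")
}

#' Write a set of counts into a cache file
#'
#' Convenience for priming a snapshot cache from a named vector.
#'
#' @param counts Named numeric vector (names are query strings).
#' @param path Cache TSV file.
#' @param date Snapshot date string.
#' @return `path`, invisibly.
#' @export
write_count_cache <- function(counts, path, date = format(Sys.Date())) {
  tab <- data.frame(query = names(counts), count = as.numeric(counts),
                    date = date, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- live source ------------------------------------------------------------

#' Live E-utilities count source
#'
#' Queries the NCBI esearch endpoint for the nucleotide database with
#' `rettype=count` (no records are downloaded), honouring a politeness delay
#' (default 3 requests/s at most) and bounded retries. An email address is
#' required by the E-utilities usage policy. Intended for interactive snapshot
#' refreshes only; wrap it in a [cache_source()] so runs are reproducible.
#'
#' @param email Contact email (required).
#' @param delay Minimum seconds between requests (default 0.34).
#' @param retries Retry attempts on transient failure (default 3).
#' @param db Entrez database (default `"nuccore"`).
#' @return A count source.
#' @export
live_source <- function(email, delay = 0.34, retries = 3, db = "nuccore") {
  stopifnot(is.character(email), length(email) == 1L, grepl("@", email))
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("live mode requires the 'xml2' package", call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$last_request <- Sys.time() - delay
  structure(
    list(email = email, delay = delay, retries = retries, db = db, env = env),
    class = c("live_source", "count_source")
  )
}

#' @export
fetch_count.live_source <- function(query, source) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi?db=",
    source$db, "&rettype=count&email=", utils::URLencode(source$email, TRUE),
    "&term=", utils::URLencode(query, reserved = TRUE)
  )
  for (attempt in seq_len(source$retries)) {
    wait <- source$delay - as.numeric(Sys.time() - source$env$last_request, "secs")
    if (wait > 0) Sys.sleep(wait)
    source$env$last_request <- Sys.time()
    res <- tryCatch({
      doc <- xml2::read_xml(url)
      as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "//Count")))
    }, error = function(e) e)
    if (is.numeric(res) && !is.na(res)) {
      return(new_count_result(query, res, "live"))
    }
    if (attempt == source$retries) {
      stop("live count fetch failed after ", source$retries,
           " attempts for query: ", query, call. = FALSE)
    }
    Sys.sleep(source$delay * 2^attempt)
  }
}
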
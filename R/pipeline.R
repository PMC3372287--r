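#' Run the full mining pipeline and write all report tables
#'
#' Orchestrates the end-to-end run: obtain (or generate) the taxa-by-descriptor
#' count matrix, then write the four report tables — raw counts with the
#' baseline column, enrichment/depletion vs. the global baseline (long and
#' paired-row wide), ranked habitat profiles with the cosmopolitanism census,
#' and the diversity/evenness index report — plus a JSON run manifest (date,
#' source, vocabulary hash, seed) so every snapshot is dated and citable.
#'
#' Any stage failure aborts with the stage name prepended to the underlying
#' error (which itself names the offending query or taxon).
#'
#' @param source A count source ([mock_source()], [cache_source()],
#'   [live_source()]), a `synthetic_spec`, or a ready-made `count_matrix`.
#' @param out_dir Output directory (created if needed).
#' @param vocab Vocabulary used to assemble the matrix from a count source;
#'   ignored for synthetic/matrix input.
#' @param precision Decimal places for reported percentages (default 2).
#' @param log_base Logarithm for the diversity report (default `"ln"`).
#' @param threshold Cosmopolitanism coverage threshold (default 0.90).
#' @return Invisibly, a named list of the files written plus the in-memory
#'   `count_matrix`.
#' @export
run_pipeline <- function(source, out_dir, vocab = load_vocabulary(),
                         precision = 2, log_base = "ln", threshold = 0.90) {
  stopifnot(precision >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- if (inherits(source, "synthetic_spec")) source$seed else NA
  m <- stage("counts", {
    if (inherits(source, "count_matrix")) {
      source
    } else if (inherits(source, "synthetic_spec")) {
      generate(source)
    } else {
      assemble_matrix(vocab, source)
    }
  })
  files <- list(
    counts = file.path(out_dir, "counts.tsv"),
    enrichment = file.path(out_dir, "enrichment_long.tsv"),
    enrichment_wide = file.path(out_dir, "enrichment_wide.tsv"),
    profiles = file.path(out_dir, "habitat_profiles.tsv"),
    census = file.path(out_dir, "cosmopolitan_census.tsv"),
    diversity = file.path(out_dir, "diversity_indices.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  stage("counts", write_count_matrix(m, files$counts))
  stage("enrichment", {
    et <- enrichment_table(m)
    write_enrichment(et, files$enrichment, files$enrichment_wide,
                     digits = precision)
  })
  stage("habitat profiles", {
    profiles <- build_profiles(m, threshold = threshold)
    write_profiles(profiles, files$profiles, files$census, digits = precision)
  })
  stage("diversity", {
    write_index_report(index_report(m, log_base = log_base), files$diversity)
  })
  stage("manifest", {
    src <- if (inherits(source, "count_matrix")) "matrix"
           else if (inherits(source, "synthetic_spec")) "synthetic"
           else class(source)[1]
    manifest <- list(
      date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      source = src,
      vocabulary_hash = vocabulary_hash(vocab),
      seed = if (is.na(seed)) NULL else seed,
      taxa = nrow(m$counts), analysis_taxa = length(m$analysis),
      descriptors = ncol(m$counts)
    )
    jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
  })
  invisible(c(files, list(matrix = m)))
}

#' Content hash of a vocabulary
#'
#' MD5 of the serialized YAML config; identifies the exact descriptor/taxon
#' roster behind a snapshot in run manifests.
#'
#' @param vocab A `vocabulary`.
#' @return Hex digest string.
#' @export
vocabulary_hash <- function(vocab) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_vocabulary(vocab, tmp)
  unname(tools::md5sum(tmp))
}
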
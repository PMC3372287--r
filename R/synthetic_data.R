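#' Specify a synthetic count matrix with known enrichment structure
#'
#' The generator emulates the statistical structure behind a
#' keyword-by-taxon record-count table: a global baseline composition over the
#' analysis taxa, and per-descriptor subcommunities whose composition is the
#' baseline reweighted by multiplicative enrichment effects. Counts are drawn
#' multinomially so each column is closed under its own total, exactly as the
#' percentage elaborations treat it.
#'
#' @param baseline_props Named probability vector over taxa (sums to 1).
#' @param baseline_depth Total baseline record count.
#' @param effects Matrix of multiplicative enrichment factors (> 0, 1 =
#'   neutral); rows = taxa (matching `baseline_props`), columns = descriptors.
#' @param column_depths Records per descriptor column (recycled); each is
#'   capped at `baseline_depth`.
#' @param seed Integer seed; fixed seed gives bit-identical matrices.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(baseline_props, baseline_depth, effects,
                           column_depths, seed = 1L) {
  stopifnot(is.numeric(baseline_props), !is.null(names(baseline_props)))
  if (any(baseline_props < 0) || abs(sum(baseline_props) - 1) > 1e-9) {
    stop("baseline_props must be non-negative and sum to 1", call. = FALSE)
  }
  effects <- as.matrix(effects)
  if (is.null(rownames(effects))) rownames(effects) <- names(baseline_props)
  stopifnot(identical(rownames(effects), names(baseline_props)),
            !is.null(colnames(effects)))
  if (any(effects <= 0)) stop("all effects must be > 0", call. = FALSE)
  column_depths <- rep_len(column_depths, ncol(effects))
  column_depths <- pmin(column_depths, baseline_depth)
  structure(
    list(baseline_props = baseline_props, baseline_depth = baseline_depth,
         effects = effects, column_depths = column_depths,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Default synthetic specification
#'
#' 29 analysis taxa with baseline proportions echoing the published ranking of
#' the global database metacommunity (Firmicutes at 26%, Gammaproteobacteria
#' nearly as abundant, Actinobacteria at about 11.8%, Bacteroidetes at about
#' 3.8%, Chlamydiae at about 1.6%; the remaining taxa share the rest equally),
#' and 12 descriptors with a handful of planted enrichment effects of the
#' magnitude seen in that study (e.g. a strong reducing-conditions enrichment
#' of Deltaproteobacteria, an oxidizing-conditions enrichment of
#' Betaproteobacteria). Illustrative only: real annotation sparsity, synonym
#' misses and keyword false positives are not modelled.
#'
#' @param seed Integer seed.
#' @param baseline_depth,column_depths Sampling depths.
#' @return A `synthetic_spec`.
#' @export
default_synthetic_spec <- function(seed = 1L, baseline_depth = 2e6,
                                   column_depths = 1e5) {
  v <- load_vocabulary()
  taxa <- analysis_taxa(v)
  props <- stats::setNames(rep(NA_real_, length(taxa)), taxa)
  props[c("Firmicutes", "Gammaproteobacteria", "Actinobacteria",
          "Alphaproteobacteria", "Betaproteobacteria", "Bacteroidetes",
          "Cyanobacteria", "Deltaproteobacteria", "Chlamydiae")] <-
    c(0.260, 0.246, 0.118, 0.090, 0.070, 0.038, 0.030, 0.025, 0.016)
  rest <- is.na(props)
  props[rest] <- (1 - sum(props, na.rm = TRUE)) / sum(rest)
  descs <- c("Soil", "Forest", "Seawater", "Sediment", "Hydrothermal",
             "Oxidizing", "Reducing", "Feces", "Rumen", "Mouth",
             "Activated sludge", "Desert")
  f <- matrix(1, length(taxa), length(descs), dimnames = list(taxa, descs))
  f["Acidobacteria", "Soil"] <- 6
  f["Actinobacteria", c("Soil", "Forest", "Desert")] <- c(1.8, 1.6, 1.5)
  f["Cyanobacteria", c("Seawater", "Desert")] <- c(8, 10)
  f["Gammaproteobacteria", "Seawater"] <- 1.5
  f["Betaproteobacteria", c("Oxidizing", "Activated sludge")] <- c(8, 4)
  f["Deltaproteobacteria", c("Reducing", "Sediment")] <- c(20, 4)
  f["Epsilonproteobacteria", "Hydrothermal"] <- 12
  f["Zetaproteobacteria", c("Hydrothermal", "Oxidizing")] <- c(15, 8)
  f["Firmicutes", c("Feces", "Rumen")] <- c(2, 2)
  f["Bacteroidetes", c("Feces", "Rumen")] <- c(5, 4)
  f["Synergistetes", "Mouth"] <- 6
  f["Dictyoglomi", "Rumen"] <- 8
  synthetic_spec(props, baseline_depth, f, column_depths, seed)
}

#' Generate a count matrix from a synthetic specification
#'
#' Baseline counts are one multinomial draw of size `baseline_depth` from
#' `baseline_props`; each descriptor column is a multinomial draw of its depth
#' from the baseline proportions reweighted by that column's effects. Columns
#' violating the containment invariant (a cell exceeding its taxon's baseline)
#' are redrawn; with column depths well below the baseline depth this is rare.
#'
#' @param spec A `synthetic_spec`.
#' @param max_redraws Redraw attempts per column before giving up.
#' @return A `count_matrix` whose rows are all analysis taxa.
#' @export
generate <- function(spec, max_redraws = 100L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  taxa <- names(spec$baseline_props)
  baseline <- as.vector(stats::rmultinom(1, spec$baseline_depth,
                                         spec$baseline_props))
  names(baseline) <- taxa
  counts <- sapply(seq_len(ncol(spec$effects)), function(j) {
    p <- spec$baseline_props * spec$effects[, j]
    p <- p / sum(p)
    for (try in seq_len(max_redraws)) {
      n <- as.vector(stats::rmultinom(1, spec$column_depths[j], p))
      if (all(n <= baseline)) return(n)
    }
    stop("could not satisfy containment for descriptor column '",
         colnames(spec$effects)[j],
         "'; lower its column depth relative to the baseline depth",
         call. = FALSE)
  })
  dimnames(counts) <- dimnames(spec$effects)
  count_matrix(counts, baseline, analysis = taxa)
}

#' Closed-form expected enrichment of a synthetic specification
#'
#' The expected subcommunity proportion of taxon i under descriptor d is
#' `p_sub = p_i f_id / sum_j(p_j f_jd)`; net variation and fold change follow
#' as in [enrichment_table()] (on the percentage scale). These are the
#' infinite-depth values the empirical enrichment converges to.
#'
#' @param spec A `synthetic_spec`.
#' @return A long data.frame: `taxon`, `descriptor`, `p_base`, `p_sub`, `net`,
#'   `fold` (percent scale for the percentage columns).
#' @export
expected_enrichment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$baseline_props
  out <- lapply(colnames(spec$effects), function(d) {
    w <- p * spec$effects[, d]
    p_sub <- 100 * w / sum(w)
    p_base <- 100 * p
    data.frame(taxon = names(p), descriptor = d, p_base = unname(p_base),
               p_sub = unname(p_sub), net = unname(p_sub - p_base),
               fold = unname(ifelse(p_base == 0, NA_real_, p_sub / p_base)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a synthetic specification to YAML or JSON
#'
#' Same config dialect as the vocabulary; [read_synthetic_spec()] round-trips.
#'
#' @param spec A `synthetic_spec`.
#' @param path Output file (`.json` for JSON, else YAML).
#' @return `path`, invisibly.
#' @export
write_synthetic_spec <- function(spec, path) {
  x <- list(
    baseline_props = as.list(spec$baseline_props),
    baseline_depth = spec$baseline_depth,
    descriptors = colnames(spec$effects),
    effects = apply(spec$effects, 1, as.list, simplify = FALSE),
    column_depths = spec$column_depths,
    seed = spec$seed
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Read a synthetic specification written by [write_synthetic_spec()]
#'
#' @param path Input file.
#' @return A `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  props <- unlist(x$baseline_props)
  descs <- unlist(x$descriptors)
  eff <- t(vapply(names(props), function(t) unlist(x$effects[[t]]),
                  numeric(length(descs))))
  colnames(eff) <- descs
  synthetic_spec(props, x$baseline_depth, eff, unlist(x$column_depths),
                 x$seed)
}
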
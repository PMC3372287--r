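#' Construct a habitat/condition descriptor
#'
#' A descriptor is a named habitat, host, or physico-chemical condition
#' expressed as a set of synonymous free-text search words (e.g. "Hydrothermal
#' OR geothermal"), optionally with exclusion phrases subtracted from matches
#' (e.g. excluding "Salt Lake City" from the "Lake" descriptor so that author
#' affiliations do not count as habitat hits).
#'
#' @param label Short unique name, e.g. `"Soil"`.
#' @param terms Character vector of one or more search words/phrases. Terms
#'   must not embed Boolean operators; the query grammar adds those.
#' @param exclusions Character vector (possibly empty) of phrases to subtract
#'   from matches.
#' @return An object of class `descriptor`.
#' @examples
#' descriptor("Volcanic", c("volcano", "volcanic"))
#' descriptor("Lake", "lake", exclusions = "Salt Lake City")
#' @export
descriptor <- function(label, terms, exclusions = character()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  terms <- as.character(terms)
  if (length(terms) < 1L || any(!nzchar(terms))) {
    stop("descriptor '", label, "': terms must be a non-empty list of non-empty strings",
         call. = FALSE)
  }
  bad <- grepl("\\b(AND|OR|NOT)\\b", terms)
  if (any(bad)) {
    stop("descriptor '", label, "': term contains a Boolean operator: ",
         paste(terms[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    list(label = label, terms = terms, exclusions = as.character(exclusions)),
    class = "descriptor"
  )
}

#' @export
print.descriptor <- function(x, ...) {
  cat("<descriptor>", x$label, ": ", expand_descriptor(x), "\n", sep = "")
  invisible(x)
}

#' Construct a taxonomic query unit
#'
#' A taxon addressable in the organism-restricted clause of a query: a
#' bacterial phylum, a proteobacterial class, a superkingdom, or a pseudo-taxon
#' addressed by free text only (here "uncultured", which is a description-line
#' label rather than an organism-field entry).
#'
#' @param name Taxon label.
#' @param rank One of `"phylum"`, `"class"`, `"superkingdom"`, `"pseudo"`.
#' @param organism_term Text for the `[Organism]` clause; defaults to `name`.
#'   Must be empty exactly when `rank = "pseudo"`.
#' @return An object of class `taxon_query`.
#' @examples
#' taxon_query("Actinobacteria", "phylum")
#' taxon_query("uncultured", "pseudo")
#' @export
taxon_query <- function(name, rank = c("phylum", "class", "superkingdom", "pseudo"),
                        organism_term = NULL) {
  rank <- match.arg(rank)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(organism_term)) {
    organism_term <- if (rank == "pseudo") "" else name
  }
  if ((rank == "pseudo") != !nzchar(organism_term)) {
    stop("taxon '", name, "': rank is 'pseudo' iff organism_term is empty",
         call. = FALSE)
  }
  structure(
    list(name = name, rank = rank, organism_term = organism_term),
    class = "taxon_query"
  )
}

#' @export
print.taxon_query <- function(x, ...) {
  cat("<taxon_query> ", x$name, " [", x$rank, "]\n", sep = "")
  invisible(x)
}

# ---- default registries ----------------------------------------------------

# Multi-term descriptors follow the published synonym footnotes verbatim;
# single-term descriptors are those named in the running text. The original
# study used 48 descriptor sets; 42 are reconstructable, so users wanting the
# exact original roster supply a config (see load_vocabulary).
default_descriptors <- function() {
  d <- list(
    descriptor("Soil", "soil"),
    descriptor("Forest", "forest"),
    descriptor("Desert", "desert"),
    descriptor("Agriculture", c("agriculture", "crop")),
    descriptor("Grassland", c("grassland", "prairie")),
    descriptor("Pasture", "pasture"),
    descriptor("Alpine", c("alpine", "mountain")),
    descriptor("Wetland", c("wetland", "marsh", "wetlands", "marshes")),
    descriptor("Lake", "lake", exclusions = "Salt Lake City"),
    descriptor("Seawater", c("seawater", "sea", "marine", "ocean")),
    descriptor("Sediment", "sediment"),
    descriptor("Aquifer-cave", c("aquifer", "groundwater", "karst", "cave")),
    descriptor("Hydrothermal", c("hydrothermal", "geothermal")),
    descriptor("Volcanic", c("volcanic", "volcano")),
    descriptor("Atmosphere", c("atmosphere", "atmospheric")),
    descriptor("Halophilic", c("halophilic", "salt", "saline")),
    descriptor("Psychrophilic",
               c("psychrophilic", "ice", "glacier", "glacial", "arctic", "permafrost")),
    descriptor("Thermophilic", "thermophilic"),
    descriptor("Acid", c("acid", "acidic", "acidophilic")),
    descriptor("Alkaline", c("alkaline", "alkaliphilic")),
    descriptor("Anaerobic", c("anaerobic", "anaerobe", "anaerobes")),
    descriptor("Oxidizing", "oxidizing"),
    descriptor("Reducing", "reducing"),
    descriptor("Symbiont", c("symbiont", "symbiotic")),
    descriptor("Endophyte", c("endophyte", "endophytic")),
    descriptor("Rhizosphere", c("rhizosphere", "root", "rhizospheric")),
    descriptor("Phyllosphere", c("phyllosphere", "phyllospheric", "leaf", "leaves")),
    descriptor("Plants", "plants"),
    descriptor("Insect", c("insect", "larvae", "moth")),
    descriptor("Cow", c("cow", "bovine", "cattle", "calf")),
    descriptor("Rumen", c("rumen", "ruminal")),
    descriptor("Intestinal", c("intestinal", "intestine", "gastrointestinal")),
    descriptor("Mouth", c("mouth", "oral", "buccal")),
    descriptor("Feces", c("feces", "faeces", "fecal")),
    descriptor("Human", "human"),
    descriptor("Clinical", "clinical"),
    descriptor("Antibiotic", c("antibiotic", "antibiotics")),
    descriptor("Degrading", c("degrading", "degradation", "degradative")),
    descriptor("Polluted", c("polluted", "pollution")),
    descriptor("Activated sludge", "activated sludge"),
    descriptor("Food", "food"),
    descriptor("Resistant", "resistant")
  )
  names(d) <- vapply(d, `[[`, character(1), "label")
  d
}

# 23 non-Proteobacteria phyla (three of them candidate phyla awaiting
# placement, handled as ordinary entries), the Proteobacteria umbrella, its six
# classes, the Archaea superkingdom and the "uncultured" pseudo-taxon. The 29
# analysis units are the 23 phyla plus the 6 classes.
default_taxa <- function() {
  phyla <- c(
    "Acidobacteria", "Actinobacteria", "Aquificae", "Armatimonadetes",
    "Bacteroidetes", "Caldiserica", "Chlamydiae", "Chlorobi", "Chloroflexi",
    "Cyanobacteria", "Deinococcus-Thermus", "Dictyoglomi", "Fibrobacteres",
    "Firmicutes", "Fusobacteria", "Gemmatimonadetes", "Lentisphaerae",
    "Nitrospirae", "Planctomycetes", "Spirochaetes", "Synergistetes",
    "Thermotogae", "Verrucomicrobia"
  )
  classes <- paste0(
    c("Alpha", "Beta", "Gamma", "Delta", "Epsilon", "Zeta"), "proteobacteria"
  )
  t <- c(
    lapply(phyla, taxon_query, rank = "phylum"),
    list(taxon_query("Proteobacteria", "phylum")),
    lapply(classes, taxon_query, rank = "class"),
    list(
      taxon_query("Archaea", "superkingdom"),
      taxon_query("uncultured", "pseudo")
    )
  )
  names(t) <- vapply(t, `[[`, character(1), "name")
  t
}

#' Load a vocabulary of descriptors and taxa
#'
#' Without a config this returns the default registry: 42 habitat/condition
#' descriptors reconstructed from the published synonym sets, and 32 taxon
#' query units (23 non-Proteobacteria phyla, the Proteobacteria umbrella, the
#' six proteobacterial classes alpha- through zeta-, the Archaea superkingdom
#' and the "uncultured" pseudo-taxon). A config document (YAML or JSON, schema
#' `{descriptors: [{label, terms, exclusions}], taxa: [{name, rank,
#' organism_term}]}`) adds new entries or overrides defaults by label/name.
#'
#' The original study screened 48 descriptor sets; only the 42 named in the
#' published text are reconstructable, so matching or altering the exact
#' original roster requires a user config.
#'
#' @param config Path to a YAML/JSON file, or a pre-parsed list with elements
#'   `descriptors` and/or `taxa`, or `NULL` for the defaults.
#' @param base Vocabulary to extend; defaults to the built-in registry. Pass
#'   `NULL` to build purely from `config`.
#' @return An object of class `vocabulary` with elements `descriptors` and
#'   `taxa` (named lists).
#' @examples
#' v <- load_vocabulary()
#' length(v$descriptors)
#' v$descriptors[["Feces"]]$terms
#' @export
load_vocabulary <- function(config = NULL, base = "default") {
  desc <- list()
  taxa <- list()
  if (identical(base, "default")) {
    desc <- default_descriptors()
    taxa <- default_taxa()
  }
  if (!is.null(config)) {
    cfg <- parse_vocab_config(config)
    for (d in cfg$descriptors) desc[[d$label]] <- d
    for (t in cfg$taxa) taxa[[t$name]] <- t
  }
  validate_vocabulary(new_vocabulary(desc, taxa))
}

new_vocabulary <- function(descriptors, taxa) {
  structure(list(descriptors = descriptors, taxa = taxa), class = "vocabulary")
}

validate_vocabulary <- function(v) {
  lab <- tolower(vapply(v$descriptors, `[[`, character(1), "label"))
  if (anyDuplicated(lab)) {
    stop("duplicate descriptor labels (case-insensitive): ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "), call. = FALSE)
  }
  nm <- tolower(vapply(v$taxa, `[[`, character(1), "name"))
  if (anyDuplicated(nm)) {
    stop("duplicate taxon names (case-insensitive): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  v
}

parse_vocab_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a file path or a list", call. = FALSE)
  parse_one <- function(x, what, ctor) {
    tryCatch(ctor(x), error = function(e) {
      stop("malformed ", what, " entry '",
           if (!is.null(x$label)) x$label else if (!is.null(x$name)) x$name else "?",
           "': ", conditionMessage(e), call. = FALSE)
    })
  }
  list(
    descriptors = lapply(config$descriptors, parse_one, what = "descriptor",
                         ctor = function(x) {
                           if (is.null(x$label) || is.null(x$terms)) {
                             stop("needs 'label' and 'terms'")
                           }
                           descriptor(x$label, unlist(x$terms),
                                      exclusions = unlist(x$exclusions %||% character()))
                         }),
    taxa = lapply(config$taxa, parse_one, what = "taxon",
                  ctor = function(x) {
                    if (is.null(x$name)) stop("needs 'name'")
                    taxon_query(x$name, rank = x$rank %||% "phylum",
                                organism_term = x$organism_term)
                  })
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a vocabulary to YAML or JSON
#'
#' Writes the `{descriptors, taxa}` config schema; reloading the file with
#' [load_vocabulary()] (with `base = NULL`) round-trips the structure.
#'
#' @param v A `vocabulary`.
#' @param path Output file; format chosen by extension (`.json` else YAML).
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(v, path) {
  stopifnot(inherits(v, "vocabulary"))
  x <- list(
    descriptors = lapply(unname(v$descriptors), function(d) {
      list(label = d$label, terms = as.list(d$terms),
           exclusions = as.list(d$exclusions))
    }),
    taxa = lapply(unname(v$taxa), function(t) {
      list(name = t$name, rank = t$rank, organism_term = t$organism_term)
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Names of the analysis taxa in a vocabulary
#'
#' The analysis taxa are the units over which community sums, percentages and
#' indices run: phyla and proteobacterial classes, excluding the Proteobacteria
#' umbrella (whose records are already covered by its six classes), the Archaea
#' superkingdom, and pseudo-taxa. With the default registry this is 29 units.
#'
#' @param v A `vocabulary`.
#' @return Character vector of taxon names.
#' @export
analysis_taxa <- function(v) {
  stopifnot(inherits(v, "vocabulary"))
  keep <- vapply(v$taxa, function(t) {
    t$rank %in% c("phylum", "class") && t$name != "Proteobacteria"
  }, logical(1))
  unname(vapply(v$taxa[keep], `[[`, character(1), "name"))
}

#' Expand a descriptor into its Boolean clause
#'
#' Joins the synonym terms with OR inside parentheses; exclusion phrases, if
#' any, are appended as a `NOT (e1 OR e2 ...)` group.
#'
#' @param d A `descriptor`.
#' @return The clause as a single string, e.g. `"(volcano OR volcanic)"`.
#' @examples
#' expand_descriptor(descriptor("Volcanic", c("volcano", "volcanic")))
#' @export
expand_descriptor <- function(d) {
  stopifnot(inherits(d, "descriptor"))
  clause <- paste0("(", paste(d$terms, collapse = " OR "), ")")
  if (length(d$exclusions)) {
    excl <- paste0("(", paste(d$exclusions, collapse = " OR "), ")")
    clause <- paste(clause, "NOT", excl)
  }
  clause
}
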
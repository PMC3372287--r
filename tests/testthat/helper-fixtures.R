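# Small matrices built in code for the unit and property tests.

# The worked-example matrix: the five printed record counts, with the
# remaining bacteria aggregated into one synthetic analysis row so that the
# column sums equal the printed totals.
worked_example_matrix <- function() {
  counts <- matrix(
    c(20870, 100094 - 20870, 0, 0), nrow = 4, ncol = 1,
    dimnames = list(c("Actinobacteria", "OtherBacteria", "Archaea",
                      "uncultured"), "Soil")
  )
  count_matrix(counts,
               baseline = c(157719, 1338869 - 157719, 180441, 2143037))
}

# A deterministic 5-taxon x 3-descriptor matrix with Archaea + uncultured rows.
small_matrix <- function() {
  taxa <- c("A", "B", "C", "D", "E", "Archaea", "uncultured")
  counts <- matrix(
    c(50, 30, 20, 0, 10, 4, 80,
      10, 10, 10, 10, 10, 2, 30,
      0,  0, 90,  0,  5, 0, 40),
    nrow = 7, dimnames = list(taxa, c("d1", "d2", "d3"))
  )
  count_matrix(counts, baseline = c(200, 150, 300, 40, 60, 20, 500))
}

# A tiny vocabulary whose every query can be primed in a mock/cache source.
tiny_vocab <- function() {
  load_vocabulary(base = NULL, config = list(
    descriptors = list(
      list(label = "Soil", terms = list("soil")),
      list(label = "Feces", terms = list("feces", "faeces", "fecal"))
    ),
    taxa = list(
      list(name = "Actinobacteria", rank = "phylum"),
      list(name = "Firmicutes", rank = "phylum"),
      list(name = "Archaea", rank = "superkingdom"),
      list(name = "uncultured", rank = "pseudo")
    )
  ))
}

# Prime every query of a vocabulary with deterministic counts.
prime_counts <- function(vocab, baseline = 1000, sub = 10) {
  counts <- c()
  for (t in vocab$taxa) {
    counts[build_query(NULL, t)] <- baseline
    for (d in vocab$descriptors) {
      counts[build_query(d, t)] <- sub
    }
  }
  counts
}

# Random valid count matrix under a fixed seed (for property loops).
random_matrix <- function(n_taxa = 5, n_desc = 4) {
  taxa <- paste0("t", seq_len(n_taxa))
  baseline <- stats::setNames(sample(200:1000, n_taxa), taxa)
  counts <- sapply(seq_len(n_desc), function(j) {
    vapply(baseline, function(N) sample(0:N, 1), numeric(1))
  })
  dimnames(counts) <- list(taxa, paste0("d", seq_len(n_desc)))
  count_matrix(counts, baseline, archaea = NA_character_,
               uncultured = NA_character_)
}
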
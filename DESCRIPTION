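Package: phylokey
Title: Phylum-Habitat Association Mining from Nucleotide-Database Keyword Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines taxon-habitat associations from record counts returned by
    Boolean keyword queries against a nucleotide sequence database. Builds
    descriptor-by-taxon Boolean queries, assembles a phylum-by-descriptor
    count matrix from a pluggable count source (live E-utilities, cached
    snapshot, or mock), and derives three elaborations: baseline-relative
    enrichment and depletion of each taxon under each habitat descriptor,
    per-taxon habitat preference profiles with a cosmopolitanism criterion,
    and Shannon/Simpson diversity and evenness indexing of descriptor-defined
    virtual communities. Includes a multinomial synthetic-matrix generator
    with known enrichment effects for end-to-end validation, and a
    composition-comparison utility with a Bray-Curtis dissimilarity score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    xml2
Config/testthat/edition: 3
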
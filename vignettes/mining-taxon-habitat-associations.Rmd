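---
title: "Mining taxon-habitat associations from keyword record counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining taxon-habitat associations from keyword record counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylokey)
```

## The idea

Public nucleotide databases accumulate, record by record, the habitat and host
annotations of decades of microbial ecology. A Boolean query of the form

```
(descriptor keyword OR synonymous keyword) AND <Phylum>[Organism] NOT genome
```

counts how many records of one taxon carry one habitat descriptor. Crossing
every taxon with every descriptor yields a count matrix `n[i,d]`, together
with the descriptor-free totals `N[i]` (the baseline, or "GenBank" column),
from which three views of taxon-habitat association follow. The organism-field
restriction prevents a phylum named elsewhere in an unrelated record from
counting; `NOT genome` removes genome-project records, which would otherwise
flood the counts with thousands of sequences from single strains. The one
pseudo-taxon, `uncultured`, is a description-line label rather than an
organism-field entry, so it is searched as bare free text.

The result of any such run is a snapshot of a live, growing database. The
pipeline therefore treats reproducibility as a first-class concern: counts are
fetched through a pluggable source (live E-utilities, an on-disk dated cache,
or a mock), and every `run_pipeline()` output carries a manifest with the
date, the source, and a hash of the exact vocabulary used.

## The vocabulary and its reconstruction

The default vocabulary ships 42 descriptors. The 28 multi-term synonym sets
follow the published footnotes verbatim (e.g. Feces = feces OR faeces OR
fecal; Aquifer-cave = aquifer OR groundwater OR karst OR cave, one descriptor,
not two); the 14 single-term descriptors are those named in the running text.
The original study used 48 descriptor sets, but the remaining six — and the
full exclusion lists, beyond the documented "Salt Lake City" exclusion on
Lake — appear only in supplementary material not reproduced here. Rather than
invent synonym sets, the package ships what is reconstructable and accepts a
YAML/JSON config to add or override descriptors and taxa:

```{r}
v <- load_vocabulary()
length(v$descriptors)
expand_descriptor(v$descriptors[["Lake"]])
```

The taxon registry is likewise a best reconstruction: 24 bacterial phyla
(including three candidate phyla handled as ordinary entries), of which the
Proteobacteria umbrella is resolved into its six classes (alpha- through
zeta-), plus the Archaea superkingdom and the `uncultured` pseudo-taxon. The
**analysis taxa** — the units over which all sums, percentages and indices run
— are the 23 non-Proteobacteria phyla plus the six classes: 29 units. The
umbrella row is excluded because its records are already covered by its
classes; including it would double-count. Archaea and `uncultured` are carried
for the two ratio columns only. Thirteen of the 29 units are named in the
published text; the remaining ten phyla are the standard ones of the era and
only affect a run's roster, not any algorithm.

## Enrichment relative to the database metacommunity

With `S_d = Σ_i n[i,d]` the descriptor's column sum over analysis taxa and
`S_0 = Σ_i N[i]` the baseline sum:

* baseline share `p_base[i] = 100 · N[i] / S_0`,
* subcommunity share `p_sub[i,d] = 100 · n[i,d] / S_d`,
* net variation `Δ[i,d] = p_sub − p_base` (percentage points),
* fold change `F[i,d] = p_sub / p_base`.

Because both share vectors sum to 100, the net variations in any column cancel
to zero — a conservation property the test suite checks to 1e-6 on random
matrices. Each column is closed under its own total, so columns are mutually
independent: deleting a descriptor leaves every other column's cells
bit-identical, which the tests verify literally.

Cells with `n = 0` are *absent*: net and fold are undefined markers (`NA`),
mirroring the blank-cell convention of the original tables, and "absent"
dominates any other status. Statuses `enriched`/`depleted`/`unchanged` follow
the sign of `Δ` at full precision; colour-intensity banding is a display
concern left to the caller. Reported tables are rounded half-even to 2
decimals; all internal comparisons run at full precision.

One documented inconsistency: the published worked example derives a
soil-subcommunity share of 20.81% from the printed counts 20870/100094, but
direct division gives 20.85% (and hence net +9.07 rather than the printed
+9.03). The package computes from counts; `net_variation()` is exposed on
percentage pairs so the printed pair (20.81, 11.78) → +9.03 can still be
verified as printed. The fold, 1.77, agrees either way at 2 decimals.

```{r}
m <- read_count_matrix(system.file("extdata", "worked_example_snapshot.tsv",
                                   package = "phylokey"))
et <- enrichment_table(m)
subset(et, taxon == "Actinobacteria")
```

## Habitat profiles and cosmopolitanism

The profile view asks the converse question: of all records of taxon *i*, what
share carries descriptor *d*? `h[i,d] = 100 · n[i,d] / N[i]`. Descriptors are
ranked by decreasing `h` (ties broken by label so output is deterministic);
shares may sum past 100 because descriptors overlap on records. A taxon
*linked* to at least 90% of the vocabulary's descriptors is classified
cosmopolitan. "Linked" defaults to `n ≥ 1` — the source text states no
higher floor — but `min_count` is exposed; the coverage fraction denominates
by the full descriptor roster, not by descriptors that happen to have records.
At 48 descriptors the criterion bites between 43/48 (89.6%, specific) and
44/48 (91.7%, cosmopolitan), a boundary the tests pin down.

## Diversity indexing of virtual communities

Each descriptor column, over the analysis taxa with `n > 0`, is treated as a
community with proportions `p_i`. Richness `S` counts those taxa; the indices
are Simpson concentration `D = Σ p_i²` reported as `1/D` (Hill N2, the
effective number of equally-abundant taxa), Shannon `H′ = −Σ p_i ln p_i`,
Simpson evenness `E_{1/D} = (1/D)/S`, and Pielou `J′ = H′ / ln S`. Degenerate
cases are marked, not fudged: an empty column has `S = 0` and all indices
`NA`; a monodominant column has `1/D = 1`, `H′ = 0` and `J′` undefined. The
natural logarithm is the default since the original convention is unstated;
`log2`/`log10` are available, and only `H′` rescales — `J′` is base-invariant.
Identities the suite enforces: replication invariance (doubling all counts
changes nothing), the Hill ordering `exp(H′) ≥ 1/D ≥ 1`, maximal evenness
exactly at uniform columns, and agreement with vegan's implementations as an
independent cross-check.

## The synthetic generator

Offline testing needs matrices with known structure. A `synthetic_spec` fixes
a baseline composition `π` over the taxa, a matrix of multiplicative effects
`f[i,d] > 0`, and sampling depths; `generate()` draws the baseline
multinomially at depth `B` from `π` and each descriptor column at its depth
from `normalize(π ⊙ f[,d])`. Multinomial sampling (rather than independent
Poisson) keeps each column closed under its exact total, matching how the
percentage elaborations condition on column sums. The containment invariant
`n[i,d] ≤ N[i]` is enforced by capping column depths at the baseline depth and
redrawing the rare violating column. A fixed seed gives bit-identical output,
and the generator restores the caller's RNG state.

The closed-form expectation `p_sub[i,d] = π_i f[i,d] / Σ_j π_j f[j,d]` makes
recovery testable. The default spec uses 29 taxa with baseline proportions
echoing the published metacommunity ranking (Firmicutes 26%, a nearly equal
Gammaproteobacteria share, Actinobacteria 11.8%, Bacteroidetes 3.8%,
Chlamydiae 1.6%, the rest uniform), 12 descriptors, a 2·10⁶ baseline depth and
10⁵ records per column — depths chosen to sit two orders of magnitude below
the real database so runs stay in seconds while keeping multinomial noise on
non-rare taxa below a percent. Parameter recovery is assessed on the
**replicate-mean** fold over 100 seeded replicates, the standard Monte-Carlo
estimate: a single draw at column depth 10⁵ has ~2.3% relative noise on a
2%-share taxon, so per-replicate 5% agreement is not a statistically
meaningful demand, while the mean (standard error ~0.2%) recovers every
planted effect well within 5%. What passing these tests shows is that the
*elaboration pipeline* is correct under multinomial noise; it says nothing
about annotation sparsity, synonym misses or keyword false positives in real
records, which the generator deliberately does not model.

## Composition validation

To compare a pipeline-derived subcommunity with an external survey,
compositions are filtered to major taxa (share strictly above 1%, bar-chart
semantics, deliberately not renormalized), aligned on the union of taxa with
absentees as zero, and scored with Bray-Curtis `Σ|a−b| / Σ(a+b)` — 0 for
identical compositions, 1 for disjoint ones — turning a visual "the bars
agree" claim into a thresholdable number. Multi-descriptor habitat classes
(e.g. a seawater/sea/marine/ocean merge) are approximated offline by summing
counts per taxon before forming proportions; records matching several merged
descriptors are counted once per descriptor, since deduplication requires the
live database. That approximation slightly overweights multiply-annotated
records and is documented rather than hidden.

## Numerical and design choices

* Ratios and percentages are computed at full precision; rounding (half-even,
  2 d.p. for percentage tables, 4 d.p. for indices) happens only at the
  serialization boundary.
* Undefined quantities are explicit `NA` markers with documented meaning
  (absent cell, empty community, zero-Archaea ratio), never silent zeros or
  infinities; a missing count from a source is a hard error naming the query.
* Ordering is always deterministic: decreasing value with lexicographic label
  tie-breaks.
* Case-insensitive matching is assumed throughout, as in the upstream search
  engine; terms may not embed Boolean operators — the grammar adds them.
* The test and analysis problem sizes (29 × 12 synthetic matrices, 100
  replicates at 10⁵ column depth) were chosen as the smallest sizes at which
  multinomial noise is comfortably below every tolerance being asserted.

## Limitations

The package reproduces a *method*, not a dataset: the original tables are a
dated snapshot of a live database and are not reproducible at desk scale, so
correctness is established on the printed worked example, on property suites,
and on synthetic matrices with known truth. The live source is a thin,
rate-limited E-utilities client intended for refreshing snapshots, not for
bulk mining; no statistical testing of count differences is performed (the
descriptive deviations are the method), and no ontology mapping, stemming or
term discovery is attempted — descriptor quality is the user's craft, as it
was in the original study.
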
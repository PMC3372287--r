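#!/usr/bin/env Rscript
# Diversity and evenness indexing of the descriptor-defined virtual
# communities: inverse Simpson (Hill N2), Shannon H' (nats), Simpson evenness
# E1/D and Pielou J' per descriptor, ranked by diversity.

library(phylokey)

m <- read_count_matrix("results/synthetic_snapshot.tsv")
rep <- index_report(m, sort_by = "inv_simpson")
write_index_report(rep, "results/diversity_indices.tsv")

cat("descriptor subcommunities by decreasing inverse Simpson diversity:\n")
print(transform(rep, inv_simpson = round(inv_simpson, 4),
                shannon = round(shannon, 4),
                simpson_evenness = round(simpson_evenness, 4),
                pielou = round(pielou, 4)), row.names = FALSE)
cat("descriptors with strong planted dominance (e.g. a single taxon boosted\n")
cat("20-fold) rank low on both diversity and evenness, as expected.\n")
cat("wrote results/diversity_indices.tsv\n")
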
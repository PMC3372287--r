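#!/usr/bin/env Rscript
# Habitat preference profiles: for each taxon, descriptors ranked by the share
# of the taxon's records they capture, and the cosmopolitanism census at the
# 90% linked-descriptor criterion.

library(phylokey)

m <- read_count_matrix("results/synthetic_snapshot.tsv")
profiles <- build_profiles(m, threshold = 0.90)
write_profiles(profiles, "results/habitat_profiles.tsv",
               "results/cosmopolitan_census.tsv")

census <- cosmopolitan_census(profiles)
cat(sprintf("cosmopolitan taxa: %d of %d (%.1f%%) at the 90%% criterion\n",
            census$count, census$total, census$percent))
cat("note: with only 12 synthetic descriptors and no annotation sparsity,\n")
cat("coverage is near-complete by construction; on real snapshots the census\n")
cat("separates broad from habitat-specific taxa.\n")

for (t in c("Acidobacteria", "Deltaproteobacteria")) {
  p <- profiles[[t]]
  cat(t, "- top descriptors:",
      paste(sprintf("%s (%.1f%%)", p$entries$descriptor[1:3],
                    p$entries$h[1:3]), collapse = ", "), "\n")
}
cat("wrote results/habitat_profiles.tsv, results/cosmopolitan_census.tsv\n")
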
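#!/usr/bin/env Rscript
# Worked example: the published record counts for soil-tagged Actinobacteria,
# pushed through every elaboration. Writes results/worked_example.tsv.
#
# The bundled snapshot holds the printed totals (Actinobacteria 157719 of a
# 1338869 bacterial sum; 20870 of the 100094 soil-tagged records; 2143037
# "uncultured" records; Archaea scaled to the printed 7.42 overall ratio),
# with the remaining bacteria aggregated in one synthetic "OtherBacteria" row.

library(phylokey)

snapshot <- system.file("extdata", "worked_example_snapshot.tsv",
                        package = "phylokey")
m <- read_count_matrix(snapshot)

et <- enrichment_table(m)
act <- et[et$taxon == "Actinobacteria" & et$descriptor == "Soil", ]

tab <- data.frame(
  quantity = c("baseline percentage of Actinobacteria",
               "soil-subcommunity percentage",
               "net variation (percentage points)",
               "fold change over baseline",
               "habitat percent (share of Actinobacteria records that are soil-tagged)",
               "bacteria / Archaea ratio (whole database)",
               "uncultured / bacteria ratio (whole database)"),
  value = c(round(act$p_base, 2), round(act$p_sub, 2), round(act$net, 2),
            round(act$fold, 2),
            round(habitat_percent(m, "Actinobacteria", "Soil"), 2),
            round(bacteria_over_archaea(m), 2),
            round(uncultured_ratio(m), 2))
)
print(tab, right = FALSE, row.names = FALSE)

cat("\nActinobacteria make up", tab$value[1],
    "% of phylum-classified bacterial records overall but", tab$value[2],
    "% of soil-tagged ones: a", tab$value[4], "-fold enrichment;",
    tab$value[5], "% of all Actinobacteria records carry the soil keyword.\n")

dir.create("results", showWarnings = FALSE)
write.table(tab, "results/worked_example.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("wrote results/worked_example.tsv\n")
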
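#!/usr/bin/env Rscript
# Defense-island detection: chain defense genes per contig (gaps of at most
# 10 intervening genes), keep maximal chains with >= 5 defense genes from
# >= 3 families, and census the result against the planted truth.

suppressPackageStartupMessages(library(defensome))

cohort <- read_cohort(file.path("results", "cohort"))
islands <- detect_islands_cohort(cohort)
cen <- island_census(islands)

write.table(islands, file.path("results", "islands.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(cen[c("n_islands", "total_span_genes",
                           "total_defense_genes", "defense_gene_pct")],
                     file.path("results", "census.json"), auto_unbox = TRUE,
                     pretty = TRUE)

truth <- jsonlite::read_json(file.path("results", "truth.json"),
                             simplifyVector = TRUE)
key_d <- paste(islands$genome_id, islands$first_index, islands$last_index)
key_t <- paste(truth$planted_islands$genome_id,
               truth$planted_islands$first_index,
               truth$planted_islands$last_index)
message(sprintf("islands detected: %d (planted: %d; exact-span recovery: %d/%d)",
                nrow(islands), length(key_t), sum(key_t %in% key_d),
                length(key_t)))
message(sprintf("defense genes within islands: %d of %d genes (%.1f%%)",
                cen$total_defense_genes, cen$total_span_genes,
                cen$defense_gene_pct))
part <- jsonlite::read_json(file.path("results", "partition.json"),
                            simplifyVector = TRUE)
comp <- island_family_composition(islands, cohort_systems(cohort),
                                  first_line = part$first_line)
message(sprintf("island systems: %.0f%% first-line, %.0f%% accessory",
                100 * comp$first_line_share, 100 * comp$accessory_share))
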
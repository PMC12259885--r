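#!/usr/bin/env Rscript
# CRISPR spacer -> protospacer matching on a planted phage set (<= 1
# mismatch, >= 95% spacer coverage), virus-host links, anti-defense
# tabulation over the targeted phages, and novelty classification of an
# alignment-hit table.

suppressPackageStartupMessages(library(defensome))

seed <- 20260921L
phages <- generate_phages(20, len_range = c(8000, 30000), seed = seed + 1L)
ss <- generate_spacer_set(phages, n_pos = 25, n_neg = 25, seed = seed + 2L)
hits <- find_protospacers(ss$spacers, phages, max_mm = 1, min_cov = 0.95)

write.table(hits, file.path("results", "hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

planted <- ss$truth$planted
hit_pos <- paste(hits$spacer_id, hits$phage_id, hits$phage_start, hits$strand)
plant_key <- paste(planted$spacer_id, planted$phage_id, planted$position,
                   planted$strand)
message(sprintf("planted protospacers recovered: %d/%d; negatives hit: %d",
                sum(plant_key %in% hit_pos), nrow(planted),
                sum(hits$spacer_id %in% ss$truth$negatives)))

# hosts: spacers attributed round-robin to five host genomes
origin <- setNames(sprintf("host_%02d", (seq_along(ss$spacers) - 1L) %% 5 + 1),
                   names(ss$spacers))
links <- link_hosts(hits, origin)
write.table(links, file.path("results", "links.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("virus-host links: %d pairs targeting %d distinct phages",
                nrow(links), attr(links, "n_phages_targeted")))

# anti-defense genes planted on the targeted phages (two types co-localized
# on the first targeted phage)
targeted <- unique(hits$phage_id)
anti <- do.call(rbind, lapply(seq_along(targeted), function(i)
  data.frame(genome_id = targeted[i], contig_id = targeted[i],
             gene_id = sprintf("%s_ad%d", targeted[i], i), index = i,
             start = 1L + i * 1000L, end = i * 1000L + 900L, strand = "+",
             labels = paste0("anti_defense:",
                             c("Acr", "anti-RM", "anti-Thoeris")[i %% 3 + 1]),
             stringsAsFactors = FALSE)))
anti <- rbind(anti, within(anti[1, ], {
  gene_id <- paste0(gene_id, "b"); index <- index + 1L
  labels <- "anti_defense:anti-CBASS"
}))
tl <- tally_anti_defense(anti, phage_universe_size = length(phages))
jsonlite::write_json(unclass(tl), file.path("results", "antidefense.json"),
                     auto_unbox = TRUE, pretty = TRUE)
co <- colocalized_anti_defense(anti)
message(sprintf("anti-defense: %d genes on %d/%d phages (%.1f%%); %d phage(s) with co-localized genes",
                tl$n_genes, tl$n_phages, tl$universe, tl$prevalence_pct,
                nrow(co)))

# novelty of the spacer set against the hit table (blast-style fractions)
nv <- novelty_classify(
  data.frame(query = hits$spacer_id, coverage = hits$coverage,
             identity = hits$identity, stringsAsFactors = FALSE),
  queries = names(ss$spacers))
message(sprintf("novelty at >=80%% coverage and >=90%% identity: %d known, %d novel",
                sum(nv$status == "known"), sum(nv$status == "novel")))
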
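#!/usr/bin/env Rscript
# Defensome census: per-genome profiles, family prevalence, the first-line /
# accessory partition (prevalence > 10%), the share of systems in first-line
# families, the exponential decline of the per-genome count distribution and
# the count-vs-size correlation.

suppressPackageStartupMessages(library(defensome))

cohort <- read_cohort(file.path("results", "cohort"))
prev <- prevalence(cohort)
part <- partition_first_line(prev, threshold = 0.10)
profiles <- profile_cohort(cohort, first_line = part$first_line)

write.table(profiles, file.path("results", "profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(prev, file.path("results", "prevalence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(part, file.path("results", "partition.json"),
                     auto_unbox = TRUE, pretty = TRUE)

message(sprintf("first-line families (prevalence > 10%%): %s",
                paste(part$first_line, collapse = ", ")))
message(sprintf("first-line share of all systems: %.1f%%",
                100 * family_share(cohort, part$first_line)))
decl <- fit_exponential_decline(profiles$n_systems)
message(sprintf("per-genome count distribution: exponential decline rate %.2f (R2 %.2f)",
                decl$rate, decl$r_squared))
sizes <- vapply(cohort, function(g) g$qc$size_bp, numeric(1))
sp <- ds_spearman(profiles$n_systems, sizes)
message(sprintf("systems vs genome size: Spearman rho %.2f (p %.2g)",
                sp$rho, sp$p))
message(sprintf("%d of %d genomes pass the high-quality filter",
                sum(hq_filter(cohort_qc(cohort))), length(cohort)))
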
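#!/usr/bin/env Rscript
# Colocalization of defense systems with mobile elements and islands:
# compartment assignment (all-genes containment, ICE > integron > prophage >
# plasmid priority), observed/expected enrichment with Yates-corrected
# chi-square tests, and compartment densities per kb.

suppressPackageStartupMessages(library(defensome))

cohort <- read_cohort(file.path("results", "cohort"))
sys <- cohort_systems(cohort)
sysc <- assign_compartments(sys, cohort_genes(cohort), cohort_mges(cohort))
oem <- oe_table(sysc$family, sysc$compartment)
islands <- detect_islands_cohort(cohort)
oei <- island_oe_table(sys, islands)
dens <- compartment_density(sysc, cohort_mges(cohort), cohort_qc(cohort))

write.table(as.data.frame(oem), file.path("results", "oe_mge.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(as.data.frame(oei), file.path("results", "oe_islands.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(dens, file.path("results", "densities.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

mge <- dens[dens$compartment != "chromosome" & dens$total_bp > 0, ]
chr <- dens$density_per_kb[dens$compartment == "chromosome"]
message(sprintf("defense density: %.4f per kb on MGEs vs %.4f on chromosomes (ratio %.1f)",
                sum(mge$n_systems) / (sum(mge$total_bp) / 1000), chr,
                (sum(mge$n_systems) / (sum(mge$total_bp) / 1000)) / chr))
part <- jsonlite::read_json(file.path("results", "partition.json"),
                            simplifyVector = TRUE)
acc_di <- !oei$family %in% part$first_line & oei$compartment == "DI"
fl_di <- oei$family %in% part$first_line & oei$compartment == "DI"
message(sprintf("island O/E: accessory %.2f, first-line %.2f",
                sum(oei$observed[acc_di]) / sum(oei$expected[acc_di]),
                sum(oei$observed[fl_di]) / sum(oei$expected[fl_di])))
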
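#!/usr/bin/env Rscript
# Defense vs adaptive-trait trade-off: per-count upper envelope of ARG
# numbers, multi-start logistic ceiling fit, and Spearman correlations per
# system category, compared with the planted parameters.

suppressPackageStartupMessages(library(defensome))

cohort <- read_cohort(file.path("results", "cohort"))
part <- jsonlite::read_json(file.path("results", "partition.json"),
                            simplifyVector = TRUE)
env <- build_envelope(cohort, trait = "ARG", category = "all")
fit <- fit_sigmoid(env, seed = 20260921L)
corr <- category_correlations(cohort, trait = "ARG",
                              first_line = part$first_line)

write.table(as.data.frame(env), file.path("results", "envelope.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(unclass(fit), file.path("results", "fit.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
write.table(corr, file.path("results", "correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json(file.path("results", "truth.json"),
                             simplifyVector = TRUE)
tp <- truth$tradeoff_params$ARG
message(sprintf("envelope fit: a=%.1f b=%.2f c=%.1f (planted %g/%g/%g), R2=%.3f",
                fit$a, fit$b, fit$c, tp[["a"]], tp[["b"]], tp[["c"]],
                fit$r_squared))
message(sprintf("Spearman rho(ARG, systems): all %.2f, first-line %.2f, accessory %.2f",
                corr$rho[corr$category == "all"],
                corr$rho[corr$category == "first_line"],
                corr$rho[corr$category == "accessory"]))
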
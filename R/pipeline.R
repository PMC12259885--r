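#' Default configuration of the end-to-end defensome analysis
#'
#' Stage parameters default to the analysis' reference values: island
#' chaining at max_gap 10 / 5 defense genes / 3 families, first-line
#' prevalence threshold 0.10, all-genes MGE containment with Yates-corrected
#' chi-square, spacer matching at <= 1 mismatch and >= 95% coverage.
#'
#' @return a named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    cohort_dir = NULL,      # read an existing cohort directory; NULL simulates
    simulate = list(n_genomes = 150L,
                    genome_size = list(meanlog = log(8e5), sdlog = 0.35)),
    first_line_threshold = 0.10,
    named_first_line = NULL,
    max_gap = 10L, min_def_genes = 5L, min_families = 3L,
    gap_semantics = "intervening",
    containment = "all",
    priority = c("ice_ime", "integron", "phage_prophage", "plasmid"),
    chi_correction = TRUE,
    trait = "ARG", category = "all", min_bin = 1L, n_starts = 16L,
    spacers = list(enabled = TRUE, n_phages = 12L, n_pos = 10L, n_neg = 10L,
                   max_mm = 1L, min_cov = 0.95, fasta = NULL),
    out_dir = "defensome_run"
  )
}

.merge_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (k %in% c("simulate", "spacers") && is.list(config[[k]])) {
      unknown2 <- setdiff(names(config[[k]]), names(base[[k]]))
      if (length(unknown2))
        stop("unknown configuration key(s) under ", k, ": ",
             paste(unknown2, collapse = ", "))
      base[[k]][names(config[[k]])] <- config[[k]]
    } else base[[k]] <- config[[k]]
  }
  base
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full defensome analysis
#'
#' Executes metrics, island detection, colocalization, trade-off fitting and
#' (optionally) spacer matching in order, over a simulated or previously
#' written cohort, and writes tab-separated stage outputs plus a
#' machine-readable `summary.json` and a `manifest.json` recording every
#' resolved parameter. Configuration is validated before any stage runs.
#' All randomised steps derive their seeds from `config$seed`, so two runs
#' with the same configuration produce identical outputs.
#'
#' @param config a (partial) configuration list; see [default_config()].
#' @return the summary list, invisibly.
#' @export
run_defensome_analysis <- function(config = list()) {
  cfg <- .merge_config(config)
  # validation before any stage runs
  if (!is.null(cfg$cohort_dir)) {
    need <- file.path(cfg$cohort_dir,
                      c("genes.tsv", "systems.tsv", "mges.tsv", "qc.tsv",
                        "traits.tsv"))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop("configuration error: missing cohort file(s): ",
           paste(miss, collapse = ", "))
  }
  if (isTRUE(cfg$spacers$enabled) && !is.null(cfg$spacers$fasta) &&
      !file.exists(cfg$spacers$fasta))
    stop("configuration error: spacer fasta not found: ", cfg$spacers$fasta)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  jw <- function(x, f) jsonlite::write_json(x, file.path(cfg$out_dir, f),
                                            auto_unbox = TRUE, digits = NA,
                                            pretty = TRUE)

  cohort <- .stage("input", {
    if (is.null(cfg$cohort_dir)) {
      params <- do.call(cohort_params, c(cfg$simulate, list(seed = cfg$seed)))
      generate_cohort(params)$cohort
    } else read_cohort(cfg$cohort_dir)
  })

  metrics <- .stage("metrics", {
    prev <- prevalence(cohort)
    part <- partition_first_line(prev, cfg$first_line_threshold,
                                 named = cfg$named_first_line)
    profiles <- profile_cohort(cohort, first_line = part$first_line)
    .write_tsv(profiles, file.path(cfg$out_dir, "profiles.tsv"))
    .write_tsv(prev, file.path(cfg$out_dir, "prevalence.tsv"))
    jw(part, "partition.json")
    list(prev = prev, part = part, profiles = profiles)
  })

  islands <- .stage("islands", {
    isl <- detect_islands_cohort(cohort, max_gap = cfg$max_gap,
                                 min_def_genes = cfg$min_def_genes,
                                 min_families = cfg$min_families,
                                 gap_semantics = cfg$gap_semantics)
    cen <- island_census(isl)
    .write_tsv(isl, file.path(cfg$out_dir, "islands.tsv"))
    jw(cen[c("n_islands", "total_span_genes", "total_defense_genes",
             "defense_gene_pct")], "census.json")
    isl
  })

  sys <- cohort_systems(cohort)
  coloc <- .stage("coloc", {
    if (!nrow(sys)) {
      .write_tsv(data.frame(), file.path(cfg$out_dir, "oe_mge.tsv"))
      .write_tsv(data.frame(), file.path(cfg$out_dir, "oe_islands.tsv"))
      .write_tsv(data.frame(), file.path(cfg$out_dir, "densities.tsv"))
      NULL
    } else {
      sysc <- assign_compartments(sys, cohort_genes(cohort),
                                  cohort_mges(cohort),
                                  priority = cfg$priority,
                                  containment = cfg$containment)
      oem <- oe_table(sysc$family, sysc$compartment,
                      correct = cfg$chi_correction)
      oei <- island_oe_table(sys, islands, correct = cfg$chi_correction)
      dens <- compartment_density(sysc, cohort_mges(cohort), cohort_qc(cohort))
      .write_tsv(as.data.frame(oem), file.path(cfg$out_dir, "oe_mge.tsv"))
      .write_tsv(as.data.frame(oei), file.path(cfg$out_dir, "oe_islands.tsv"))
      .write_tsv(dens, file.path(cfg$out_dir, "densities.tsv"))
      list(oe_mge = oem, oe_islands = oei, densities = dens)
    }
  })

  fit <- .stage("tradeoff", {
    env <- tryCatch(build_envelope(cohort, trait = cfg$trait,
                                   category = cfg$category,
                                   first_line = metrics$part$first_line,
                                   min_bin = cfg$min_bin),
                    error = function(e) NULL)
    f <- if (!is.null(env) && nrow(env) >= 4)
      fit_sigmoid(env, n_starts = cfg$n_starts, seed = cfg$seed + 101L)
    else NULL
    if (!is.null(env))
      .write_tsv(as.data.frame(env), file.path(cfg$out_dir, "envelope.tsv"))
    jw(if (is.null(f)) list(converged = FALSE) else unclass(f), "fit.json")
    corr <- if (length(cohort) >= 4)
      category_correlations(cohort, trait = cfg$trait,
                            first_line = metrics$part$first_line) else NULL
    if (!is.null(corr))
      .write_tsv(corr, file.path(cfg$out_dir, "correlations.tsv"))
    f
  })

  sp <- if (isTRUE(cfg$spacers$enabled)) .stage("spacers", {
    phages <- if (!is.null(cfg$spacers$fasta)) read_fasta(cfg$spacers$fasta)
      else generate_phages(cfg$spacers$n_phages, seed = cfg$seed + 211L)
    ss <- generate_spacer_set(phages, cfg$spacers$n_pos, cfg$spacers$n_neg,
                              seed = cfg$seed + 307L)
    hits <- find_protospacers(ss$spacers, phages,
                              max_mm = cfg$spacers$max_mm,
                              min_cov = cfg$spacers$min_cov)
    .write_tsv(hits, file.path(cfg$out_dir, "hits.tsv"))
    hits
  }) else NULL

  summary <- list(
    n_genomes = length(cohort),
    n_genes = nrow(cohort_genes(cohort)),
    n_systems = nrow(sys),
    n_families = length(unique(sys$family)),
    first_line = metrics$part$first_line,
    first_line_share = if (nrow(sys))
      family_share(cohort, metrics$part$first_line) else NA,
    n_islands = nrow(islands),
    island_defense_gene_pct = island_census(islands)$defense_gene_pct,
    sigmoid_fit = if (is.null(fit)) NULL
      else fit[c("a", "b", "c", "r_squared", "converged")],
    n_spacer_hits = if (is.null(sp)) NULL else nrow(sp)
  )
  jw(summary, "summary.json")
  jw(list(package_version = as.character(utils::packageVersion("defensome")),
          config = cfg[setdiff(names(cfg), "out_dir")]),
     "manifest.json")
  invisible(summary)
}
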
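#' Per-genome defensome profile
#'
#' Counts defense systems and distinct families and computes the system
#' density in systems per Mbp of assembly. When a first-line family set is
#' supplied the system count is partitioned into first-line and accessory
#' components (they always sum to the total).
#'
#' @param genome a `genome_annotation`.
#' @param first_line character vector of first-line family names.
#' @return one-row data frame: genome_id, n_systems, density_per_mb,
#'   n_families, first_line_count, accessory_count.
#' @export
profile_genome <- function(genome, first_line = character(0)) {
  stopifnot(genome$qc$size_bp > 0)
  n <- nrow(genome$systems)
  fl <- sum(genome$systems$family %in% first_line)
  data.frame(genome_id = genome$qc$genome_id, n_systems = n,
             density_per_mb = n / (genome$qc$size_bp / 1e6),
             n_families = length(unique(genome$systems$family)),
             first_line_count = fl, accessory_count = n - fl,
             stringsAsFactors = FALSE)
}

#' @rdname profile_genome
#' @param cohort a `defensome_cohort`.
#' @export
profile_cohort <- function(cohort, first_line = character(0)) {
  out <- do.call(rbind, lapply(cohort, profile_genome, first_line = first_line))
  rownames(out) <- NULL
  out
}

#' Defense-family prevalence across a cohort
#'
#' Prevalence of a family is the fraction of genomes carrying at least one
#' system of that family; a genome with several systems of the family counts
#' once. `total_systems` counts every system, so the column sums to the
#' cohort-wide system count.
#'
#' @param cohort a non-empty `defensome_cohort`.
#' @return data frame (family, n_genomes, prevalence, total_systems), sorted
#'   by decreasing prevalence.
#' @export
prevalence <- function(cohort) {
  if (!length(cohort)) stop("prevalence of an empty cohort is undefined")
  sys <- cohort_systems(cohort)
  if (!nrow(sys))
    return(data.frame(family = character(0), n_genomes = integer(0),
                      prevalence = numeric(0), total_systems = integer(0),
                      stringsAsFactors = FALSE))
  per_gen <- unique(sys[c("genome_id", "family")])
  ng <- table(per_gen$family)
  tot <- table(sys$family)
  fam <- names(ng)
  out <- data.frame(family = fam, n_genomes = as.integer(ng[fam]),
                    prevalence = as.integer(ng[fam]) / length(cohort),
                    total_systems = as.integer(tot[fam]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prevalence, out$family), ]
  rownames(out) <- NULL
  out
}

#' Partition families into first-line and accessory
#'
#' The rule form labels families with prevalence strictly greater than the
#' threshold (default 10% of genomes) as first-line and the remainder as
#' accessory. Passing `named` replicates a fixed published partition instead
#' of the rule.
#'
#' @param prev a prevalence table from [prevalence()].
#' @param threshold prevalence fraction; strict `>` applies.
#' @param named optional character vector of first-line family names.
#' @return list with `first_line` and `accessory` character vectors (disjoint,
#'   jointly covering the table).
#' @export
partition_first_line <- function(prev, threshold = 0.10, named = NULL) {
  if (!is.null(named)) {
    fl <- intersect(prev$family, named)
  } else {
    fl <- prev$family[prev$prevalence > threshold]
  }
  list(first_line = fl, accessory = setdiff(prev$family, fl))
}

#' Share of systems belonging to a family set
#' @param cohort a `defensome_cohort` with at least one system.
#' @param families character vector of family names.
#' @return fraction of all systems whose family is in the set.
#' @export
family_share <- function(cohort, families) {
  sys <- cohort_systems(cohort)
  if (!nrow(sys)) stop("family_share undefined: cohort has no systems")
  mean(sys$family %in% families)
}

#' High-quality MAG filter
#'
#' A genome passes iff completeness > 90, contamination < 5,
#' completeness - 5 x contamination > 70 and N50 > 100 kb; all four
#' comparisons are strict.
#'
#' @param qc data frame with columns completeness, contamination, n50_bp
#'   (one or more rows).
#' @return logical vector.
#' @export
hq_filter <- function(qc) {
  qc$completeness > 90 & qc$contamination < 5 &
    (qc$completeness - 5 * qc$contamination) > 70 & qc$n50_bp > 100000
}

#' Exponential-decline fit of the defense-system count distribution
#'
#' Least-squares line through (k, log f_k) over count bins k with positive
#' frequency f_k; the decline rate is the negative slope. Zero-frequency bins
#' are skipped, not imputed.
#'
#' @param counts integer vector of per-genome defense-system counts.
#' @return list with `rate` and `r_squared`.
#' @export
fit_exponential_decline <- function(counts) {
  tab <- table(factor(counts, levels = 0:max(counts)))
  k <- as.integer(names(tab))[tab > 0]
  f <- as.integer(tab)[tab > 0]
  if (length(k) < 3) stop("need at least 3 non-empty count bins")
  fit <- stats::lm(log(f) ~ k)
  # summary() warns on numerically perfect fits; those are legitimate here
  list(rate = -unname(stats::coef(fit)[2]),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average-rank handling of ties; two-sided p from the t approximation with
#' n - 2 degrees of freedom (via `stats::cor.test(..., exact = FALSE)`).
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `rho` and `p`.
#' @export
ds_spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
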
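#' Assign defense systems to genomic compartments
#'
#' A system is assigned to an MGE class iff the midpoint of every member gene
#' lies within a single interval of that class (`containment = "all"`, the
#' default) or more than half of the member-gene midpoints do
#' (`"majority"`). When several classes qualify (overlapping MGE calls) the
#' first class in `priority` wins; otherwise the system is chromosomal. With
#' non-overlapping MGE annotations the result does not depend on the
#' priority order.
#'
#' @param systems pooled systems table.
#' @param genes pooled gene table (for coordinates).
#' @param mges pooled MGE interval table.
#' @param priority ordered character vector of MGE classes.
#' @param containment `"all"` or `"majority"`.
#' @return `systems` with an added `compartment` column.
#' @export
assign_compartments <- function(systems, genes, mges,
                                priority = c("ice_ime", "integron",
                                             "phage_prophage", "plasmid"),
                                containment = c("all", "majority")) {
  containment <- match.arg(containment)
  if (!nrow(systems)) {
    systems$compartment <- character(0)
    return(systems)
  }
  mid <- (genes$start + genes$end) / 2
  names(mid) <- genes$gene_id
  gene_contig <- stats::setNames(genes$contig_id, genes$gene_id)
  comp <- character(nrow(systems))
  for (i in seq_len(nrow(systems))) {
    ids <- .split_ids(systems$gene_ids[i])
    ctg <- unique(gene_contig[ids])
    comp[i] <- "chromosome"
    if (length(ctg) != 1L || !nrow(mges)) next
    m <- mid[ids]
    cand <- mges[mges$contig_id == ctg, , drop = FALSE]
    if (!nrow(cand)) next
    frac <- vapply(seq_len(nrow(cand)), function(j)
      mean(m >= cand$start[j] & m <= cand$end[j]), numeric(1))
    ok <- if (containment == "all") frac == 1 else frac > 0.5
    classes <- unique(cand$mge_class[ok])
    if (length(classes))
      comp[i] <- priority[min(match(classes, priority))]
  }
  systems$compartment <- comp
  systems
}

#' Observed/expected colocalization table with chi-square tests
#'
#' For each family f and compartment c the expected count under independence
#' is E = total_f x total_c / N (the family total times the fraction of all
#' systems assigned to the compartment). Each cell is tested with a
#' two-sided chi-square on the 2x2 table
#' \[\[O, total_f - O\], \[total_c - O, N - total_f - total_c + O\]\], with
#' Yates continuity correction by default. A Benjamini-Hochberg column is
#' provided alongside the raw p-values.
#'
#' @param families character vector, one entry per system.
#' @param compartments character vector parallel to `families`.
#' @param correct apply Yates continuity correction.
#' @return data frame of class `oe_table` (family, compartment, observed,
#'   expected, ratio, chi2, p, p_bh) with margin attributes
#'   `family_totals`, `compartment_totals` and `grand_total`.
#' @export
oe_table <- function(families, compartments, correct = TRUE) {
  stopifnot(length(families) == length(compartments))
  if (!length(families)) stop("O/E table undefined for zero systems")
  O <- table(families, compartments)
  rf <- rowSums(O); cf <- colSums(O); N <- sum(O)
  cells <- expand.grid(family = rownames(O), compartment = colnames(O),
                       stringsAsFactors = FALSE)
  cells$observed <- as.integer(O[cbind(cells$family, cells$compartment)])
  cells$expected <- rf[cells$family] * cf[cells$compartment] / N
  cells$ratio <- ifelse(cells$expected > 0, cells$observed / cells$expected,
                        NA_real_)
  stat <- mapply(function(o, f, c) {
    m <- matrix(c(o, rf[[f]] - o, cf[[c]] - o, N - rf[[f]] - cf[[c]] + o),
                nrow = 2, byrow = TRUE)
    ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
    c(unname(ht$statistic), ht$p.value)
  }, cells$observed, cells$family, cells$compartment)
  cells$chi2 <- stat[1, ]
  cells$p <- stat[2, ]
  cells$p_bh <- stats::p.adjust(cells$p, method = "BH")
  rownames(cells) <- NULL
  structure(cells, class = c("oe_table", "data.frame"),
            family_totals = rf, compartment_totals = cf, grand_total = N)
}

#' O/E table of defense systems vs defense islands
#'
#' Same mathematics as [oe_table()] with the two compartments `DI` (system
#' assigned to a detected defense island) and `non_DI`.
#'
#' @param systems pooled systems table.
#' @param islands island table from [detect_islands_cohort()].
#' @param correct apply Yates continuity correction.
#' @return an `oe_table`.
#' @export
island_oe_table <- function(systems, islands, correct = TRUE) {
  in_di <- unique(unlist(lapply(islands$systems, .split_ids)))
  comp <- ifelse(systems$system_id %in% in_di, "DI", "non_DI")
  oe_table(systems$family, comp, correct = correct)
}

# merge 1-based inclusive intervals; returns total covered bp
.covered_bp <- function(start, end) {
  if (!length(start)) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce + 1) ce <- max(ce, end[i])
    else { tot <- tot + (ce - cs + 1); cs <- start[i]; ce <- end[i] }
  }
  tot + (ce - cs + 1)
}

#' Defense-system density per compartment
#'
#' Systems per kb for the chromosome and each MGE class, cohort-wide.
#' Per-class lengths merge overlapping intervals within the class; the
#' chromosomal length is the total genome size minus the merged length of
#' all MGEs.
#'
#' @param systems_with_comp systems table with a `compartment` column (from
#'   [assign_compartments()]).
#' @param mges pooled MGE interval table.
#' @param qc pooled QC table (for genome sizes).
#' @return data frame (compartment, n_systems, total_bp, density_per_kb).
#' @export
compartment_density <- function(systems_with_comp, mges, qc) {
  cls_bp <- vapply(.mge_classes, function(cl) {
    sub <- mges[mges$mge_class == cl, , drop = FALSE]
    if (!nrow(sub)) return(0)
    sum(vapply(split(sub, paste(sub$genome_id, sub$contig_id)), function(s)
      .covered_bp(s$start, s$end), numeric(1)))
  }, numeric(1))
  all_bp <- if (nrow(mges))
    sum(vapply(split(mges, paste(mges$genome_id, mges$contig_id)), function(s)
      .covered_bp(s$start, s$end), numeric(1))) else 0
  chr_bp <- sum(qc$size_bp) - all_bp
  comps <- c("chromosome", .mge_classes)
  bp <- c(chromosome = chr_bp, cls_bp)
  n <- vapply(comps, function(cl)
    sum(systems_with_comp$compartment == cl), numeric(1))
  if (any(bp <= 0 & n > 0))
    stop("compartment with zero length but assigned systems: ",
         paste(comps[bp <= 0 & n > 0], collapse = ", "))
  data.frame(compartment = comps, n_systems = as.integer(n),
             total_bp = unname(bp),
             density_per_kb = ifelse(bp > 0, n / (bp / 1000), 0),
             stringsAsFactors = FALSE, row.names = NULL)
}
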
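.empty_islands <- function() {
  data.frame(genome_id = character(0), contig_id = character(0),
             first_index = integer(0), last_index = integer(0),
             span_genes = integer(0), n_defense = integer(0),
             families = character(0), defense_gene_ids = character(0),
             systems = character(0), stringsAsFactors = FALSE)
}

#' Detect defense islands in one genome
#'
#' A defense gene is any gene belonging to at least one defense system.
#' Per contig, defense genes in index order are chained greedily: a chain
#' extends while the number of intervening non-defense genes between
#' consecutive defense genes is at most `max_gap` (default semantics
#' `"intervening"`; `"index-diff"` instead requires the index difference
#' itself to be at most `max_gap`). Maximal chains are retained as islands
#' iff they contain at least `min_def_genes` defense genes from at least
#' `min_families` distinct families. Islands never cross contigs. A system
#' belongs to an island if at least one (`system_containment = "any"`) or
#' all (`"all"`) of its member genes lie within the island span.
#'
#' @param genome a `genome_annotation`.
#' @param max_gap maximum gap between consecutive defense genes.
#' @param min_def_genes minimum number of defense genes per island.
#' @param min_families minimum number of distinct defense families.
#' @param gap_semantics `"intervening"` or `"index-diff"`.
#' @param system_containment `"any"` or `"all"`.
#' @return data frame of islands sorted by (contig, first_index).
#' @export
detect_islands <- function(genome, max_gap = 10L, min_def_genes = 5L,
                           min_families = 3L,
                           gap_semantics = c("intervening", "index-diff"),
                           system_containment = c("any", "all")) {
  gap_semantics <- match.arg(gap_semantics)
  system_containment <- match.arg(system_containment)
  sys <- genome$systems
  if (!nrow(sys)) return(.empty_islands())
  genes <- genome$genes
  # explode systems to (gene_id, family, system_id)
  glists <- strsplit(sys$gene_ids, ",", fixed = TRUE)
  ex <- data.frame(gene_id = unlist(glists),
                   family = rep(sys$family, lengths(glists)),
                   system_id = rep(sys$system_id, lengths(glists)),
                   stringsAsFactors = FALSE)
  gi <- match(ex$gene_id, genes$gene_id)
  ex$contig_id <- genes$contig_id[gi]
  ex$index <- genes$index[gi]
  thr <- if (gap_semantics == "intervening") max_gap + 1L else max_gap
  out <- list()
  for (ct in unique(ex$contig_id)) {
    sub <- ex[ex$contig_id == ct, , drop = FALSE]
    idx <- sort(unique(sub$index))
    if (!length(idx)) next
    brk <- c(0L, which(diff(idx) > thr), length(idx))
    for (r in seq_len(length(brk) - 1L)) {
      run <- idx[(brk[r] + 1L):brk[r + 1L]]
      members <- sub[sub$index %in% run, , drop = FALSE]
      fams <- unique(members$family)
      if (length(run) < min_def_genes || length(fams) < min_families) next
      lo <- run[1]; hi <- run[length(run)]
      # systems intersecting the span
      sys_ct <- sys[sys$system_id %in% unique(ex$system_id[ex$contig_id == ct]),
                    , drop = FALSE]
      in_span <- vapply(sys_ct$system_id, function(sid) {
        ix <- ex$index[ex$system_id == sid]
        if (system_containment == "any") any(ix >= lo & ix <= hi)
        else all(ix >= lo & ix <= hi)
      }, logical(1))
      gene_ids <- genes$gene_id[genes$contig_id == ct][
        match(run, genes$index[genes$contig_id == ct])]
      out[[length(out) + 1L]] <- data.frame(
        genome_id = genome$qc$genome_id, contig_id = ct,
        first_index = lo, last_index = hi,
        span_genes = hi - lo + 1L, n_defense = length(run),
        families = paste(sort(fams), collapse = ","),
        defense_gene_ids = paste(gene_ids, collapse = ","),
        systems = paste(sys_ct$system_id[in_span], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_islands())
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$first_index), ]
  rownames(res) <- NULL
  res
}

#' @rdname detect_islands
#' @param cohort a `defensome_cohort`.
#' @param ... passed on to `detect_islands()`.
#' @export
detect_islands_cohort <- function(cohort, ...) {
  out <- do.call(rbind, lapply(cohort, detect_islands, ...))
  if (is.null(out)) return(.empty_islands())
  rownames(out) <- NULL
  out
}

#' Island census
#'
#' Totals and distributions over a set of detected islands, including the
#' overall defense-gene proportion: 100 x (sum of defense genes) / (sum of
#' island span genes). Undefined (NA) when there are no islands.
#'
#' @param islands island table with columns `span_genes`, `n_defense`.
#' @return list of class `island_census`.
#' @export
island_census <- function(islands) {
  n <- nrow(islands)
  ts <- sum(islands$span_genes)
  td <- sum(islands$n_defense)
  structure(list(
    n_islands = n, total_span_genes = ts, total_defense_genes = td,
    defense_gene_pct = if (ts > 0) 100 * td / ts else NA_real_,
    span_genes = islands$span_genes, n_defense = islands$n_defense),
    class = "island_census")
}

#' @export
print.island_census <- function(x, ...) {
  cat(sprintf("<island_census> %d islands, %d/%d defense genes (%s%%)\n",
              x$n_islands, x$total_defense_genes, x$total_span_genes,
              if (is.na(x$defense_gene_pct)) "NA"
              else formatC(x$defense_gene_pct, digits = 1, format = "f")))
  invisible(x)
}

#' First-line vs accessory composition of island systems
#'
#' Shares are computed over the distinct systems assigned to islands and sum
#' to one.
#'
#' @param islands island table from [detect_islands()].
#' @param systems pooled systems table (maps system_id to family).
#' @param first_line character vector of first-line family names.
#' @return list with `first_line_share` and `accessory_share`.
#' @export
island_family_composition <- function(islands, systems, first_line) {
  ids <- unique(unlist(lapply(islands$systems, .split_ids)))
  if (!length(ids)) stop("no systems contained in islands")
  fam <- systems$family[match(ids, systems$system_id)]
  fl <- mean(fam %in% first_line)
  list(first_line_share = fl, accessory_share = 1 - fl)
}
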
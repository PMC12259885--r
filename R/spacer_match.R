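.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# encode a sequence as integers; N gets a side-specific sentinel so that an N
# in either sequence always counts as a mismatch
.encode_dna <- function(s, n_code) {
  v <- utf8ToInt(toupper(s))
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("N")] <- n_code
  if (any(v > 127L) || any(lut[v] == 0L))
    stop("sequence contains characters outside A/C/G/T/N")
  lut[v]
}

# greedy best-first collapse of overlapping alignments at one locus:
# repeatedly keep the best remaining hit (fewest mismatches, then longest,
# then leftmost) and discard every remaining hit overlapping it
.collapse_hits <- function(h) {
  h <- h[order(h$mismatches, -h$aligned_len, h$phage_start), , drop = FALSE]
  keep_s <- integer(0); keep_e <- integer(0); keep <- integer(0)
  for (i in seq_len(nrow(h))) {
    s <- h$phage_start[i]; e <- s + h$aligned_len[i] - 1L
    if (!length(keep_s) || all(s > keep_e | e < keep_s)) {
      keep <- c(keep, i); keep_s <- c(keep_s, s); keep_e <- c(keep_e, e)
    }
  }
  h[sort(keep), , drop = FALSE]
}

#' Match CRISPR spacers to phage protospacers
#'
#' Exact ungapped matcher: reports every alignment of a spacer substring of
#' length at least `ceiling(min_cov * L)` (L = spacer length) against a
#' phage window, on both strands, with at most `max_mm` mismatches. An N in
#' either sequence never matches. Overlapping alignments of the same spacer
#' on the same phage and strand are collapsed to the single best (fewest
#' mismatches, then longest, then leftmost). For minus-strand hits
#' `phage_start` is the forward-strand coordinate of the window's left end.
#' Coverage is computed over the spacer (query), identity over the aligned
#' length.
#'
#' For 25-45 bp spacers at coverage >= 95% and one allowed mismatch these
#' criteria imply near-full-length ungapped matches, so no gapped alignment
#' is performed.
#'
#' @param spacers named character vector of spacer sequences.
#' @param phages named character vector of phage sequences.
#' @param max_mm maximum mismatches.
#' @param min_cov minimum query coverage fraction.
#' @return data frame (spacer_id, phage_id, phage_start, strand, aligned_len,
#'   mismatches, coverage, identity), deterministically ordered.
#' @export
find_protospacers <- function(spacers, phages, max_mm = 1L, min_cov = 0.95) {
  if (!length(spacers) || any(!nzchar(spacers)))
    stop("empty spacer sequence")
  if (is.null(names(spacers))) names(spacers) <- paste0("spacer_", seq_along(spacers))
  if (is.null(names(phages))) names(phages) <- paste0("phage_", seq_along(phages))
  phage_codes <- lapply(phages, .encode_dna, n_code = 5L)
  out <- list()
  for (sp in names(spacers)) {
    L <- nchar(spacers[[sp]])
    lmin <- as.integer(ceiling(min_cov * L))
    # enumerate distinct (pattern, strand) substrings once per spacer
    pats <- list()
    for (strand in c("+", "-")) {
      base <- if (strand == "+") spacers[[sp]] else .revcomp(spacers[[sp]])
      for (l in lmin:L) for (off in 0:(L - l)) {
        key <- paste0(strand, substr(base, off + 1L, off + l))
        if (is.null(pats[[key]]))
          pats[[key]] <- list(codes = .encode_dna(substr(base, off + 1L,
                                                         off + l),
                                                  n_code = 6L),
                              strand = strand, l = l)
      }
    }
    for (ph in names(phages)) {
      p <- phage_codes[[ph]]
      n <- length(p)
      raw <- list()
      for (pt in pats) {
        l <- pt$l
        if (l > n) next
        nw <- n - l + 1L
        mm <- integer(nw)
        q <- pt$codes
        for (j in seq_len(l))
          mm <- mm + (p[j:(j + nw - 1L)] != q[j])
        hit <- which(mm <= max_mm)
        if (length(hit))
          raw[[length(raw) + 1L]] <- data.frame(
            phage_start = hit, strand = pt$strand, aligned_len = l,
            mismatches = mm[hit], stringsAsFactors = FALSE)
      }
      if (!length(raw)) next
      raw <- do.call(rbind, raw)
      raw <- unique(raw)
      coll <- do.call(rbind, lapply(split(raw, raw$strand), .collapse_hits))
      coll$spacer_id <- sp
      coll$phage_id <- ph
      coll$coverage <- coll$aligned_len / L
      coll$identity <- (coll$aligned_len - coll$mismatches) / coll$aligned_len
      out[[length(out) + 1L]] <- coll
    }
  }
  if (!length(out))
    return(data.frame(spacer_id = character(0), phage_id = character(0),
                      phage_start = integer(0), strand = character(0),
                      aligned_len = integer(0), mismatches = integer(0),
                      coverage = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$spacer_id, res$phage_id, res$phage_start, res$strand),
             c("spacer_id", "phage_id", "phage_start", "strand",
               "aligned_len", "mismatches", "coverage", "identity")]
  rownames(res) <- NULL
  res
}

#' Virus-host link table from spacer hits
#'
#' Aggregates protospacer hits to distinct (host genome, phage) pairs with
#' supporting hit counts. The number of distinct targeted phages is attached
#' as attribute `n_phages_targeted`.
#'
#' @param hits hit table from [find_protospacers()].
#' @param spacer_origin named character vector mapping spacer_id to the host
#'   genome the spacer was extracted from.
#' @return data frame (host_genome, phage_id, n_hits).
#' @export
link_hosts <- function(hits, spacer_origin) {
  missing <- setdiff(unique(hits$spacer_id), names(spacer_origin))
  if (length(missing))
    stop("spacer(s) without a recorded host origin: ",
         paste(missing, collapse = ", "))
  if (!nrow(hits)) {
    out <- data.frame(host_genome = character(0), phage_id = character(0),
                      n_hits = integer(0), stringsAsFactors = FALSE)
    attr(out, "n_phages_targeted") <- 0L
    return(out)
  }
  host <- unname(spacer_origin[hits$spacer_id])
  key <- paste(host, hits$phage_id, sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  out <- data.frame(host_genome = parts[, 1], phage_id = parts[, 2],
                    n_hits = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$host_genome, out$phage_id), ]
  rownames(out) <- NULL
  attr(out, "n_phages_targeted") <- length(unique(out$phage_id))
  out
}

# extract anti_defense:<type> tags from a labels string
.anti_types <- function(labels) {
  tags <- .split_ids(labels)
  tags <- tags[startsWith(tags, "anti_defense:")]
  sub("^anti_defense:", "", tags)
}

#' Tally anti-defense genes across a phage set
#'
#' Counts genes tagged `anti_defense:<type>` per type, the total, the number
#' of phages carrying at least one such gene, and their prevalence as a
#' percentage of the phage universe (rounded to one decimal for reporting).
#'
#' @param phage_genes gene table of phage annotations (genome_id = phage id,
#'   `labels` carrying the anti_defense tags).
#' @param phage_universe_size total number of phages surveyed.
#' @return list of class `anti_defense_tally`: per_type, n_genes, n_phages,
#'   universe, prevalence_pct.
#' @export
tally_anti_defense <- function(phage_genes, phage_universe_size) {
  types <- lapply(phage_genes$labels, .anti_types)
  has <- lengths(types) > 0
  all_types <- unlist(types)
  carriers <- unique(phage_genes$genome_id[has])
  if (phage_universe_size < length(carriers))
    stop("phage universe (", phage_universe_size,
         ") smaller than the number of carrier phages (", length(carriers), ")")
  per_type <- if (length(all_types))
    sort(table(all_types), decreasing = TRUE) else table(character(0))
  structure(list(
    per_type = stats::setNames(as.integer(per_type), names(per_type)),
    n_genes = length(all_types), n_phages = length(carriers),
    universe = phage_universe_size,
    prevalence_pct = round(100 * length(carriers) / phage_universe_size, 1)),
    class = "anti_defense_tally")
}

#' @export
print.anti_defense_tally <- function(x, ...) {
  cat(sprintf("<anti_defense_tally> %d genes, %d types, %d/%d phages (%.1f%%)\n",
              x$n_genes, length(x$per_type), x$n_phages, x$universe,
              x$prevalence_pct))
  invisible(x)
}

#' Phages carrying co-localized anti-defense genes
#'
#' Returns the phages with at least two anti-defense genes, sorted by gene
#' count (decreasing), with the ordered anti-defense type context along each
#' phage.
#'
#' @param phage_genes gene table of phage annotations.
#' @return data frame (phage_id, n_anti_genes, context).
#' @export
colocalized_anti_defense <- function(phage_genes) {
  types <- lapply(phage_genes$labels, .anti_types)
  has <- lengths(types) > 0
  if (!any(has))
    return(data.frame(phage_id = character(0), n_anti_genes = integer(0),
                      context = character(0), stringsAsFactors = FALSE))
  sub <- phage_genes[has, , drop = FALSE]
  sub$type <- vapply(types[has], paste, character(1), collapse = "+")
  sub <- sub[order(sub$genome_id, sub$index, sub$start), ]
  agg <- split(sub$type, sub$genome_id)
  agg <- agg[lengths(agg) >= 2]
  if (!length(agg))
    return(data.frame(phage_id = character(0), n_anti_genes = integer(0),
                      context = character(0), stringsAsFactors = FALSE))
  out <- data.frame(phage_id = names(agg), n_anti_genes = lengths(agg),
                    context = vapply(agg, paste, character(1),
                                     collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_anti_genes, out$phage_id), ]
  rownames(out) <- NULL
  out
}

#' Classify query sequences as known or novel from an alignment-hit table
#'
#' A query is `known` iff at least one hit satisfies the thresholds; under
#' the default `"and"` rule both coverage >= `min_cov` and identity >=
#' `min_id` must hold, under `"or"` either suffices. Queries with no hits
#' are `novel`.
#'
#' @param hit_table data frame with columns `query`, `coverage`, `identity`
#'   (fractions in 0..1).
#' @param queries optional character vector of all queries (so that queries
#'   absent from the table are classified novel).
#' @param rule `"and"` or `"or"`.
#' @param min_cov,min_id thresholds.
#' @return data frame (query, status).
#' @export
novelty_classify <- function(hit_table, queries = NULL, rule = c("and", "or"),
                             min_cov = 0.80, min_id = 0.90) {
  rule <- match.arg(rule)
  stopifnot(all(c("query", "coverage", "identity") %in% names(hit_table)))
  if (nrow(hit_table) &&
      (any(hit_table$coverage < 0 | hit_table$coverage > 1) ||
       any(hit_table$identity < 0 | hit_table$identity > 1)))
    stop("coverage and identity must be fractions in [0, 1]")
  pass <- if (rule == "and")
    hit_table$coverage >= min_cov & hit_table$identity >= min_id
  else hit_table$coverage >= min_cov | hit_table$identity >= min_id
  known <- unique(hit_table$query[pass])
  if (is.null(queries)) queries <- unique(hit_table$query)
  data.frame(query = queries,
             status = ifelse(queries %in% known, "known", "novel"),
             stringsAsFactors = FALSE)
}
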
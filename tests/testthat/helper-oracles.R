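# shared fixtures and independent brute-force oracles

FIRST_LINE <- c("RM", "SoFIC", "CRISPR-Cas", "AbiE", "MazEF")

.empty_mges <- function() {
  data.frame(mge_id = character(0), genome_id = character(0),
             contig_id = character(0), start = integer(0), end = integer(0),
             mge_class = character(0), stringsAsFactors = FALSE)
}

.empty_systems <- function() {
  data.frame(system_id = character(0), genome_id = character(0),
             family = character(0), subtype = character(0),
             effector_type = character(0), gene_ids = character(0),
             stringsAsFactors = FALSE)
}

# one-contig genome on the 1 kbp gene grid, defense genes as 1-gene systems
toy_genome <- function(m, def_idx = integer(0), def_fam = character(0),
                       gid = "g1", mges = NULL,
                       traits = c(ARG = 0L, MRG = 0L, VFG = 0L),
                       size_bp = NULL) {
  stopifnot(length(def_idx) == length(def_fam))
  contig <- paste0(gid, "_c1")
  idx <- seq_len(m) - 1L
  genes <- data.frame(
    genome_id = gid, contig_id = contig,
    gene_id = sprintf("%s_g%05d", contig, idx), index = idx,
    start = 1L + idx * 1000L, end = idx * 1000L + 900L, strand = "+",
    labels = NA_character_, stringsAsFactors = FALSE)
  systems <- if (length(def_idx)) data.frame(
    system_id = sprintf("%s_s%03d", gid, seq_along(def_idx)), genome_id = gid,
    family = def_fam, subtype = NA_character_, effector_type = NA_character_,
    gene_ids = sprintf("%s_g%05d", contig, def_idx),
    stringsAsFactors = FALSE) else .empty_systems()
  if (is.null(size_bp)) size_bp <- m * 1000L
  qc <- data.frame(genome_id = gid, size_bp = as.integer(size_bp),
                   n50_bp = as.integer(size_bp), completeness = 95,
                   contamination = 1, domain = "Bacteria",
                   phylum = NA_character_, class = NA_character_,
                   stringsAsFactors = FALSE)
  genome_annotation(qc, genes, systems,
                    if (is.null(mges)) .empty_mges() else mges, traits)
}

# exhaustive enumeration of maximal qualifying defense-gene chains on one
# contig; def_idx sorted, fams a list of family sets per defense gene
oracle_islands <- function(def_idx, fams, max_gap = 10L, min_def = 5L,
                           min_fam = 3L) {
  n <- length(def_idx)
  out <- list()
  if (n) for (i in seq_len(n)) for (j in i:n) {
    seg <- def_idx[i:j]
    if (j > i && any(diff(seg) > max_gap + 1L)) next
    left_maximal <- i == 1L || (def_idx[i] - def_idx[i - 1L]) > max_gap + 1L
    right_maximal <- j == n || (def_idx[j + 1L] - def_idx[j]) > max_gap + 1L
    if (!left_maximal || !right_maximal) next
    if (length(seg) < min_def) next
    if (length(unique(unlist(fams[i:j]))) < min_fam) next
    out[[length(out) + 1L]] <- data.frame(first_index = seg[1],
                                          last_index = seg[length(seg)],
                                          n_defense = length(seg))
  }
  if (!length(out))
    return(data.frame(first_index = integer(0), last_index = integer(0),
                      n_defense = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$first_index), , drop = FALSE]
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# character-by-character window scan with greedy best-first collapse
oracle_protospacers <- function(spacer, sp_id, phages, max_mm = 1L,
                                min_cov = 0.95) {
  L <- nchar(spacer)
  lmin <- as.integer(ceiling(min_cov * L))
  res <- list()
  for (ph in names(phages)) {
    pch <- strsplit(phages[[ph]], "")[[1]]
    n <- length(pch)
    raw <- list()
    for (strand in c("+", "-")) {
      base <- if (strand == "+") spacer else oracle_revcomp(spacer)
      for (l in lmin:L) {
        if (l > n) next
        for (off in 0:(L - l)) {
          pat <- strsplit(substr(base, off + 1L, off + l), "")[[1]]
          for (s0 in 1:(n - l + 1L)) {
            w <- pch[s0:(s0 + l - 1L)]
            mm <- sum(w != pat | w == "N" | pat == "N")
            if (mm <= max_mm)
              raw[[length(raw) + 1L]] <- data.frame(
                phage_start = s0, strand = strand, aligned_len = l,
                mismatches = mm, stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (!length(raw)) next
    raw <- unique(do.call(rbind, raw))
    for (st in unique(raw$strand)) {
      h <- raw[raw$strand == st, , drop = FALSE]
      while (nrow(h)) {
        o <- order(h$mismatches, -h$aligned_len, h$phage_start)
        best <- h[o[1], , drop = FALSE]
        res[[length(res) + 1L]] <- cbind(spacer_id = sp_id, phage_id = ph,
                                         best, stringsAsFactors = FALSE)
        bs <- best$phage_start; be <- bs + best$aligned_len - 1L
        he <- h$phage_start + h$aligned_len - 1L
        h <- h[he < bs | h$phage_start > be, , drop = FALSE]
      }
    }
  }
  if (!length(res))
    return(data.frame(spacer_id = character(0), phage_id = character(0),
                      phage_start = integer(0), strand = character(0),
                      aligned_len = integer(0), mismatches = integer(0),
                      coverage = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out$coverage <- out$aligned_len / L
  out$identity <- (out$aligned_len - out$mismatches) / out$aligned_len
  out <- out[order(out$spacer_id, out$phage_id, out$phage_start, out$strand),
             c("spacer_id", "phage_id", "phage_start", "strand",
               "aligned_len", "mismatches", "coverage", "identity")]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

small_params <- function(seed, n_genomes = 40, n_islands = 4,
                         n_near_miss = 0, meanlog = log(4e5)) {
  cohort_params(n_genomes = n_genomes,
                genome_size = list(meanlog = meanlog, sdlog = 0.3),
                island_spec = list(n_islands = n_islands,
                                   genes_per_island = c(5, 9),
                                   gap_range = c(0, 3),
                                   families_per_island = c(3, 5),
                                   n_near_miss = n_near_miss),
                seed = seed)
}
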
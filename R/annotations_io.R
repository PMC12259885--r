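#' @importFrom utils read.delim write.table
#' @importFrom stats ave
NULL

# closed vocabulary of MGE classes
.mge_classes <- c("plasmid", "phage_prophage", "integron", "ice_ime")

.gene_cols   <- c("genome_id", "contig_id", "gene_id", "index", "start", "end",
                  "strand", "labels")
.system_cols <- c("system_id", "genome_id", "family", "subtype",
                  "effector_type", "gene_ids")
.mge_cols    <- c("mge_id", "genome_id", "contig_id", "start", "end",
                  "mge_class")
.qc_cols     <- c("genome_id", "size_bp", "n50_bp", "completeness",
                  "contamination", "domain", "phylum", "class")

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = ".", check.names = FALSE, colClasses = "character",
             comment.char = "")
}

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    v <- as.character(out[[j]])
    v[is.na(v)] <- "."
    out[[j]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# comma-joined id lists <-> character vectors ("." / NA means empty)
.split_ids <- function(x) {
  if (length(x) == 0 || is.na(x) || x == "" || x == ".") return(character(0))
  strsplit(x, ",", fixed = TRUE)[[1]]
}
.join_ids <- function(x) if (length(x) == 0) NA_character_ else paste(x, collapse = ",")

#' Read a gene table
#'
#' Reads a tab-delimited gene table with required columns `genome_id`,
#' `contig_id`, `gene_id`, `start`, `end`, `strand` and optional columns
#' `index` (0-based gene rank per contig) and `labels` (comma-joined trait
#' tags). Coordinates are 1-based inclusive. When `index` is absent, indices
#' are assigned per contig by start order.
#'
#' @param path path to a TSV file.
#' @return a data frame of gene records ordered by (genome, contig, index).
#' @export
read_gene_table <- function(path) {
  df <- .read_tsv(path)
  req <- c("genome_id", "contig_id", "gene_id", "start", "end", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("gene table missing required column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    gene_id   = df$gene_id,
    genome_id = df$genome_id,
    contig_id = df$contig_id,
    index     = if ("index" %in% names(df)) as.integer(df$index) else NA_integer_,
    start     = as.integer(df$start),
    end       = as.integer(df$end),
    strand    = df$strand,
    labels    = if ("labels" %in% names(df)) df$labels else NA_character_,
    stringsAsFactors = FALSE
  )
  bad <- which(out$end < out$start)
  if (length(bad))
    stop("start > end in gene table at line(s): ",
         paste(bad + 1L, collapse = ", "))
  bad <- which(!out$strand %in% c("+", "-"))
  if (length(bad))
    stop("invalid strand (must be + or -) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  if (all(is.na(out$index))) {
    out <- out[order(out$genome_id, out$contig_id, out$start, out$end,
                     out$gene_id), ]
    key <- paste(out$genome_id, out$contig_id, sep = "\r")
    out$index <- as.integer(ave(seq_len(nrow(out)), key, FUN = seq_along)) - 1L
  }
  out <- out[order(out$genome_id, out$contig_id, out$index), ]
  rownames(out) <- NULL
  out[.gene_cols] # fixed column order
}

#' Read a defense-systems table
#'
#' Two dialects are supported. `native` expects one row per system with
#' columns `system_id`, `genome_id`, `family`, `gene_ids` (comma-joined) and
#' optional `subtype`, `effector_type`. `defensefinder` expects the
#' DefenseFinder systems-table columns `sys_id`, `type`, `subtype` and
#' `protein_in_syst` (comma-joined protein ids), which are mapped onto the
#' native schema; `genome_id` is taken from a column of that name when
#' present, otherwise from the `genome_id` argument.
#'
#' @param path path to a TSV file.
#' @param dialect `"native"` or `"defensefinder"`.
#' @param genome_id genome identifier used when the file carries none.
#' @return a data frame of defense-system records.
#' @export
read_defense_systems <- function(path, dialect = c("native", "defensefinder"),
                                 genome_id = NULL) {
  dialect <- match.arg(dialect)
  df <- .read_tsv(path)
  if (dialect == "defensefinder") {
    req <- c("sys_id", "type", "protein_in_syst")
    miss <- setdiff(req, names(df))
    if (length(miss))
      stop("defensefinder systems table missing column(s): ",
           paste(miss, collapse = ", "))
    gid <- if ("genome_id" %in% names(df)) df$genome_id
           else rep(if (is.null(genome_id)) NA_character_ else genome_id,
                    nrow(df))
    out <- data.frame(
      system_id = df$sys_id, genome_id = gid, family = df$type,
      subtype = if ("subtype" %in% names(df)) df$subtype
                else rep(NA_character_, nrow(df)),
      effector_type = rep(NA_character_, nrow(df)),
      gene_ids = df$protein_in_syst,
      stringsAsFactors = FALSE
    )
  } else {
    req <- c("system_id", "genome_id", "family", "gene_ids")
    miss <- setdiff(req, names(df))
    if (length(miss))
      stop("systems table missing column(s): ", paste(miss, collapse = ", "))
    out <- data.frame(
      system_id = df$system_id, genome_id = df$genome_id, family = df$family,
      subtype = if ("subtype" %in% names(df)) df$subtype
                else rep(NA_character_, nrow(df)),
      effector_type = if ("effector_type" %in% names(df)) df$effector_type
                      else rep(NA_character_, nrow(df)),
      gene_ids = df$gene_ids, stringsAsFactors = FALSE
    )
  }
  dup <- unique(out$system_id[duplicated(out$system_id)])
  if (length(dup))
    stop("duplicate system_id: ", paste(dup, collapse = ", "))
  empty <- which(!nzchar(out$gene_ids) | is.na(out$gene_ids))
  if (length(empty))
    stop("system(s) with empty gene_ids: ",
         paste(out$system_id[empty], collapse = ", "))
  rownames(out) <- NULL
  out[.system_cols]
}

#' Read an MGE interval table in BED format
#'
#' BED input is 0-based half-open; records are converted to the package's
#' 1-based inclusive convention on read. The BED `name` field holds the MGE
#' class (`plasmid`, `phage_prophage`, `integron`, `ice_ime`). A canonical
#' `mge_id` (`contig:start-end:class`, 1-based) is assigned.
#'
#' @param path path to a BED file (no header).
#' @param contig_genome optional named character vector mapping contig ids to
#'   genome ids; unmapped contigs get `NA`.
#' @return a data frame of MGE interval records.
#' @export
read_mge_bed <- function(path, contig_genome = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", comment.char = "#")
  if (ncol(df) < 4)
    stop("BED file needs at least 4 columns (contig, start, end, name)")
  contig <- df[[1]]
  start <- as.integer(df[[2]]) + 1L
  end <- as.integer(df[[3]])
  cls <- df[[4]]
  bad <- which(!cls %in% .mge_classes)
  if (length(bad))
    stop("unknown mge_class at line(s) ", paste(bad, collapse = ", "), ": ",
         paste(unique(cls[bad]), collapse = ", "))
  bad <- which(end < start)
  if (length(bad))
    stop("empty/negative BED interval at line(s): ", paste(bad, collapse = ", "))
  gid <- if (is.null(contig_genome)) rep(NA_character_, length(contig))
         else unname(contig_genome[contig])
  data.frame(
    mge_id = sprintf("%s:%d-%d:%s", contig, start, end, cls),
    genome_id = gid, contig_id = contig, start = start, end = end,
    mge_class = cls, stringsAsFactors = FALSE
  )
}

#' Write MGE intervals as BED (0-based half-open), name = mge_class
#' @param mges MGE interval data frame.
#' @param path output path.
#' @export
write_mge_bed <- function(mges, path) {
  bed <- data.frame(mges$contig_id, mges$start - 1L, mges$end, mges$mge_class)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read/write FASTA sequences as a named character vector
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences over A/C/G/T/N.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path,
                              width = 70L)
}

#' Construct a genome annotation bundle
#'
#' Bundles one genome's QC record, ordered gene table, defense-system table,
#' MGE intervals, trait counts and optional virus-host ratio (VHR) into a
#' single object consumed by every analysis stage.
#'
#' @param qc one-row data frame with the `GenomeQC` columns.
#' @param genes gene table (see [read_gene_table()]).
#' @param systems defense-system table (see [read_defense_systems()]).
#' @param mges MGE interval table (see [read_mge_bed()]).
#' @param traits named non-negative integer vector (e.g. ARG, MRG, VFG).
#' @param vhr optional non-negative virus-host abundance ratio.
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(qc, genes, systems, mges,
                              traits = c(ARG = 0L, MRG = 0L, VFG = 0L),
                              vhr = NA_real_) {
  stopifnot(is.data.frame(qc), nrow(qc) == 1L, is.data.frame(genes),
            is.data.frame(systems), is.data.frame(mges))
  structure(list(qc = qc, genes = genes, systems = systems, mges = mges,
                 traits = traits, vhr = vhr),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d genes, %d systems, %d MGEs, %.2f Mbp\n",
              x$qc$genome_id, nrow(x$genes), nrow(x$systems), nrow(x$mges),
              x$qc$size_bp / 1e6))
  invisible(x)
}

#' @export
print.defensome_cohort <- function(x, ...) {
  cat(sprintf("<defensome_cohort> %d genomes, %d systems\n", length(x),
              sum(vapply(x, function(g) nrow(g$systems), integer(1)))))
  invisible(x)
}

#' Mark a list of genome annotations as a cohort
#' @param genomes list of `genome_annotation` objects.
#' @return the list with class `defensome_cohort`.
#' @export
as_cohort <- function(genomes) {
  stopifnot(all(vapply(genomes, inherits, logical(1), "genome_annotation")))
  structure(genomes, class = "defensome_cohort")
}

# rbind a per-genome component across the cohort
.cohort_table <- function(cohort, what) {
  parts <- lapply(cohort, `[[`, what)
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  if (!length(parts)) {
    empty <- if (what == "genes") .gene_cols
             else if (what == "systems") .system_cols
             else if (what == "mges") .mge_cols else .qc_cols
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(empty)),
                                         empty), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Pooled tables across a cohort
#' @param cohort a `defensome_cohort`.
#' @return a data frame pooling the requested component over all genomes.
#' @export
cohort_systems <- function(cohort) .cohort_table(cohort, "systems")

#' @rdname cohort_systems
#' @export
cohort_genes <- function(cohort) .cohort_table(cohort, "genes")

#' @rdname cohort_systems
#' @export
cohort_mges <- function(cohort) .cohort_table(cohort, "mges")

#' @rdname cohort_systems
#' @export
cohort_qc <- function(cohort) .cohort_table(cohort, "qc")

#' Validate a cohort against the data-model invariants
#'
#' Pure diagnostic: checks coordinate sanity, per-contig gene index
#' completeness (0..n-1), cross-references from systems to genes,
#' single-contig systems, MGE contig existence and class vocabulary, QC
#' ranges and trait non-negativity. Violations are reported, never raised.
#'
#' @param cohort a `defensome_cohort` or plain list of `genome_annotation`s.
#' @return a list with `counts` and a `violations` data frame.
#' @export
validate_cohort <- function(cohort) {
  viol <- list()
  add <- function(genome, check, detail)
    viol[[length(viol) + 1L]] <<- data.frame(genome_id = genome, check = check,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  n_genes <- 0L; n_sys <- 0L; n_mge <- 0L
  for (g in cohort) {
    gid <- g$qc$genome_id
    n_genes <- n_genes + nrow(g$genes)
    n_sys <- n_sys + nrow(g$systems)
    n_mge <- n_mge + nrow(g$mges)
    if (g$qc$size_bp <= 0) add(gid, "qc", "size_bp must be positive")
    if (g$qc$completeness < 0 || g$qc$completeness > 100)
      add(gid, "qc", "completeness outside [0, 100]")
    if (g$qc$contamination < 0) add(gid, "qc", "negative contamination")
    bad <- g$genes$end < g$genes$start
    if (any(bad))
      add(gid, "gene_coords", paste("start > end for",
                                    paste(g$genes$gene_id[bad], collapse = ",")))
    for (ct in unique(g$genes$contig_id)) {
      idx <- sort(g$genes$index[g$genes$contig_id == ct])
      if (!identical(idx, seq_along(idx) - 1L))
        add(gid, "gene_index",
            paste0("contig ", ct, ": indices not a permutation of 0..n-1"))
    }
    known <- g$genes$gene_id
    gene_contig <- stats::setNames(g$genes$contig_id, g$genes$gene_id)
    for (i in seq_len(nrow(g$systems))) {
      ids <- .split_ids(g$systems$gene_ids[i])
      missing <- setdiff(ids, known)
      if (length(missing))
        add(gid, "system_gene_ref",
            paste0(g$systems$system_id[i], ": unresolved gene(s) ",
                   paste(missing, collapse = ",")))
      ctgs <- unique(gene_contig[intersect(ids, known)])
      if (length(ctgs) > 1)
        add(gid, "system_contig",
            paste0(g$systems$system_id[i], " spans contigs ",
                   paste(ctgs, collapse = ",")))
    }
    if (nrow(g$mges)) {
      unknown <- setdiff(unique(g$mges$contig_id), unique(g$genes$contig_id))
      if (length(unknown))
        add(gid, "mge_contig",
            paste("MGE on unknown contig:", paste(unknown, collapse = ",")))
      badc <- !g$mges$mge_class %in% .mge_classes
      if (any(badc))
        add(gid, "mge_class",
            paste("unknown class:",
                  paste(unique(g$mges$mge_class[badc]), collapse = ",")))
    }
    if (any(g$traits < 0)) add(gid, "traits", "negative trait count")
  }
  violations <- if (length(viol)) do.call(rbind, viol)
    else data.frame(genome_id = character(0), check = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  list(counts = c(genomes = length(cohort), genes = n_genes,
                  systems = n_sys, mges = n_mge),
       violations = violations)
}

#' Write / read a cohort directory
#'
#' A cohort directory holds `genes.tsv`, `systems.tsv`, `mges.tsv`, `qc.tsv`
#' and `traits.tsv` (genome_id, ARG, MRG, VFG, vhr). All tables are TSV with
#' fixed column order, 1-based inclusive coordinates and `.` for missing
#' values; `write_cohort()` followed by `read_cohort()` reproduces the
#' records field by field.
#'
#' @param cohort a `defensome_cohort`.
#' @param dir directory path (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a `defensome_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(.cohort_table(cohort, "genes"), file.path(dir, "genes.tsv"))
  .write_tsv(.cohort_table(cohort, "systems"), file.path(dir, "systems.tsv"))
  .write_tsv(.cohort_table(cohort, "mges"), file.path(dir, "mges.tsv"))
  .write_tsv(.cohort_table(cohort, "qc"), file.path(dir, "qc.tsv"))
  traits <- do.call(rbind, lapply(cohort, function(g)
    data.frame(genome_id = g$qc$genome_id, ARG = g$traits[["ARG"]],
               MRG = g$traits[["MRG"]], VFG = g$traits[["VFG"]],
               vhr = g$vhr, stringsAsFactors = FALSE)))
  .write_tsv(traits, file.path(dir, "traits.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  systems <- read_defense_systems(file.path(dir, "systems.tsv"), "native")
  mdf <- .read_tsv(file.path(dir, "mges.tsv"))
  mges <- data.frame(mge_id = mdf$mge_id, genome_id = mdf$genome_id,
                     contig_id = mdf$contig_id, start = as.integer(mdf$start),
                     end = as.integer(mdf$end), mge_class = mdf$mge_class,
                     stringsAsFactors = FALSE)
  qdf <- .read_tsv(file.path(dir, "qc.tsv"))
  qc <- data.frame(genome_id = qdf$genome_id, size_bp = as.integer(qdf$size_bp),
                   n50_bp = as.integer(qdf$n50_bp),
                   completeness = as.numeric(qdf$completeness),
                   contamination = as.numeric(qdf$contamination),
                   domain = qdf$domain, phylum = qdf$phylum, class = qdf$class,
                   stringsAsFactors = FALSE)
  tdf <- .read_tsv(file.path(dir, "traits.tsv"))
  genomes <- lapply(seq_len(nrow(qc)), function(i) {
    gid <- qc$genome_id[i]
    ti <- match(gid, tdf$genome_id)
    genome_annotation(
      qc = qc[i, , drop = FALSE],
      genes = genes[genes$genome_id == gid, , drop = FALSE],
      systems = systems[systems$genome_id == gid, , drop = FALSE],
      mges = mges[mges$genome_id == gid, , drop = FALSE],
      traits = c(ARG = as.integer(tdf$ARG[ti]), MRG = as.integer(tdf$MRG[ti]),
                 VFG = as.integer(tdf$VFG[ti])),
      vhr = as.numeric(tdf$vhr[ti])
    )
  })
  genomes <- lapply(genomes, function(g) {
    rownames(g$genes) <- NULL; rownames(g$systems) <- NULL
    rownames(g$mges) <- NULL; rownames(g$qc) <- NULL
    g
  })
  as_cohort(genomes)
}
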
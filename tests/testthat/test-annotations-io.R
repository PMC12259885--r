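test_that("gene tables round-trip with explicit indices and assign them by start order otherwise", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tcontig_id\tgene_id\tindex\tstart\tend\tstrand",
               "g1\tc1\ta\t0\t1\t900\t+",
               "g1\tc1\tb\t1\t1001\t1900\t-",
               "g1\tc1\tc\t2\t2001\t2900\t+"), tf)
  g <- read_gene_table(tf)
  expect_equal(nrow(g), 3)
  expect_equal(g$index, 0:2)
  expect_equal(g$gene_id, c("a", "b", "c"))

  # same file, no index column, rows shuffled: indices follow start order
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand",
               "g1\tc1\tc\t2001\t2900\t+",
               "g1\tc1\ta\t1\t900\t+",
               "g1\tc1\tb\t1001\t1900\t-"), tf2)
  g2 <- read_gene_table(tf2)
  expect_equal(g2$gene_id, c("a", "b", "c"))
  expect_equal(g2$index, 0:2)
})

test_that("gene table errors carry the offending line and column names", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand",
               "g1\tc1\ta\t1\t900\t+",
               "g1\tc1\tb\t1900\t1001\t-"), tf)
  expect_error(read_gene_table(tf), "line\\(s\\): 3")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tcontig_id\tgene_id\tstart\tend", "g1\tc1\ta\t1\t900"),
             tf2)
  expect_error(read_gene_table(tf2), "strand")
})

test_that("defensefinder dialect maps columns and splits protein lists", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sys_id\ttype\tsubtype\tprotein_in_syst",
               "s1\tRM\tType_II\tp1,p2,p3"), tf)
  s <- read_defense_systems(tf, dialect = "defensefinder", genome_id = "g1")
  expect_equal(nrow(s), 1)
  expect_equal(s$family, "RM")
  expect_equal(s$genome_id, "g1")
  expect_equal(.split_ids(s$gene_ids), c("p1", "p2", "p3"))

  # empty file with header -> empty list
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sys_id\ttype\tsubtype\tprotein_in_syst", tf2)
  expect_equal(nrow(read_defense_systems(tf2, dialect = "defensefinder")), 0)

  # duplicate ids are named in the error
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sys_id\ttype\tsubtype\tprotein_in_syst",
               "dup1\tRM\t.\tp1", "dup1\tCBASS\t.\tp2"), tf3)
  expect_error(read_defense_systems(tf3, dialect = "defensefinder"), "dup1")
})

test_that("BED MGE input is converted from 0-based half-open coordinates", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t0\t1000\tplasmid", "c1\t5000\t8000\tphage_prophage"), tf)
  m <- read_mge_bed(tf, contig_genome = c(c1 = "g1"))
  expect_equal(m$start, c(1L, 5001L))
  expect_equal(m$end, c(1000L, 8000L))
  expect_equal(m$genome_id, c("g1", "g1"))
  tf2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t0\t1000\tmystery_element", tf2)
  expect_error(read_mge_bed(tf2), "mystery_element")
})

test_that("a generated cohort survives a write/read round trip field by field", {
  res <- generate_cohort(small_params(seed = 5, n_genomes = 6, n_islands = 1))
  dir <- withr::local_tempdir()
  write_cohort(res$cohort, dir)
  back <- read_cohort(dir)
  expect_equal(length(back), length(res$cohort))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$qc, res$cohort[[i]]$qc)
    expect_equal(back[[i]]$genes, res$cohort[[i]]$genes)
    expect_equal(back[[i]]$systems, res$cohort[[i]]$systems)
    expect_equal(back[[i]]$mges, res$cohort[[i]]$mges)
    expect_equal(back[[i]]$traits, res$cohort[[i]]$traits)
    expect_equal(back[[i]]$vhr, res$cohort[[i]]$vhr)
  }
  # gene indices stay a permutation of 0..n-1 per contig after the read path
  g <- cohort_genes(back)
  for (ct in unique(g$contig_id)) {
    idx <- sort(g$index[g$contig_id == ct])
    expect_identical(idx, seq_along(idx) - 1L)
  }
})

test_that("validate_cohort reports violations without raising", {
  res <- generate_cohort(small_params(seed = 6, n_genomes = 2, n_islands = 0))
  rep0 <- validate_cohort(res$cohort)
  expect_equal(nrow(rep0$violations), 0)
  expect_equal(unname(rep0$counts["genomes"]), 2)

  broken <- res$cohort
  # point a system at a gene that does not exist
  if (nrow(broken[[1]]$systems)) {
    broken[[1]]$systems$gene_ids[1] <- "ghost_gene"
  } else {
    broken[[1]]$systems <- data.frame(
      system_id = "sX", genome_id = broken[[1]]$qc$genome_id, family = "RM",
      subtype = NA_character_, effector_type = NA_character_,
      gene_ids = "ghost_gene", stringsAsFactors = FALSE)
  }
  # and an MGE on an unknown contig
  broken[[2]]$mges <- rbind(broken[[2]]$mges, data.frame(
    mge_id = "bad", genome_id = broken[[2]]$qc$genome_id,
    contig_id = "no_such_contig", start = 1L, end = 1000L,
    mge_class = "plasmid", stringsAsFactors = FALSE))
  rep1 <- validate_cohort(broken)
  expect_true(any(rep1$violations$check == "system_gene_ref" &
                  grepl("ghost_gene", rep1$violations$detail)))
  expect_true(any(rep1$violations$check == "mge_contig" &
                  grepl("no_such_contig", rep1$violations$detail)))
})
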
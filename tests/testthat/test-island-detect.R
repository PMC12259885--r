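test_that("island detection follows the chaining rule on hand-built contigs", {
  expect_equal(nrow(detect_islands(toy_genome(100))), 0)

  # 5 consecutive defense genes, 4 families -> one island spanning 5 genes
  g <- toy_genome(100, def_idx = 30:34,
                  def_fam = c("A", "B", "C", "D", "A"))
  isl <- detect_islands(g)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$first_index, 30)
  expect_equal(isl$last_index, 34)
  expect_equal(isl$span_genes, 5)
  expect_equal(isl$n_defense, 5)

  # 4 defense genes from 3 families: fails the minimum-gene rule
  g2 <- toy_genome(100, def_idx = c(0, 3, 7, 12),
                   def_fam = c("A", "B", "C", "A"))
  expect_equal(nrow(detect_islands(g2)), 0)

  # 6 clustered defense genes, one family: fails the family rule
  g3 <- toy_genome(100, def_idx = 10:15, def_fam = rep("RM", 6))
  expect_equal(nrow(detect_islands(g3)), 0)

  # gap semantics: 11-gene index difference = 10 intervening genes chains
  # under "intervening" but breaks under "index-diff"
  g4 <- toy_genome(100, def_idx = c(0, 11, 22, 33, 44),
                   def_fam = c("A", "B", "C", "D", "E"))
  expect_equal(nrow(detect_islands(g4)), 1)
  expect_equal(nrow(detect_islands(g4, gap_semantics = "index-diff")), 0)
})

test_that("detection equals the exhaustive maximal-chain oracle on random contigs", {
  set.seed(401)
  for (case in seq_len(250)) {
    m <- sample(20:200, 1)
    nd <- sample(0:min(m, 25), 1)
    def_idx <- sort(sample(0:(m - 1), nd))
    fam <- sample(LETTERS[1:6], nd, replace = TRUE)
    g <- toy_genome(m, def_idx, fam)
    got <- detect_islands(g)
    want <- oracle_islands(def_idx, as.list(fam))
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$first_index, want$first_index)
      expect_equal(got$last_index, want$last_index)
      expect_equal(got$n_defense, want$n_defense)
    }
  }
})

test_that("island detection is monotone in the three thresholds", {
  # raising max_gap can merge two qualifying islands into one, so the island
  # COUNT is not monotone in the gap; the defense genes covered by islands
  # are: every island at a smaller gap lies inside an island at a larger gap.
  covered <- function(isl)
    unlist(mapply(seq, isl$first_index, isl$last_index, SIMPLIFY = FALSE))
  set.seed(402)
  for (case in seq_len(40)) {
    m <- sample(60:200, 1)
    nd <- sample(5:25, 1)
    def_idx <- sort(sample(0:(m - 1), nd))
    fam <- sample(LETTERS[1:5], nd, replace = TRUE)
    g <- toy_genome(m, def_idx, fam)
    n <- function(...) nrow(detect_islands(g, ...))
    for (gaps in list(c(4, 10), c(10, 20))) {
      lo <- detect_islands(g, max_gap = gaps[1])
      hi <- detect_islands(g, max_gap = gaps[2])
      expect_true(all(covered(lo) %in% covered(hi)))
    }
    expect_gte(n(min_def_genes = 4), n(min_def_genes = 5))
    expect_gte(n(min_def_genes = 5), n(min_def_genes = 7))
    expect_gte(n(min_families = 2), n(min_families = 3))
    expect_gte(n(min_families = 3), n(min_families = 4))
  }
})

test_that("planted islands are recovered with exact spans (precision = recall = 1)", {
  for (s in c(51, 52, 53)) {
    res <- generate_cohort(small_params(seed = s, n_genomes = 40,
                                        n_islands = 5))
    isl <- detect_islands_cohort(res$cohort)
    truth <- res$truth$planted_islands
    key_d <- paste(isl$genome_id, isl$contig_id, isl$first_index,
                   isl$last_index)
    key_t <- paste(truth$genome_id, truth$contig_id, truth$first_index,
                   truth$last_index)
    expect_setequal(key_d, key_t)
  }
})

test_that("the census aggregates spans, defense genes and their proportion", {
  res <- generate_cohort(small_params(seed = 61, n_genomes = 30, n_islands = 4))
  isl <- detect_islands_cohort(res$cohort)
  cen <- island_census(isl)
  expect_equal(cen$n_islands, nrow(isl))
  expect_equal(cen$total_defense_genes, sum(isl$n_defense))
  expect_equal(cen$defense_gene_pct,
               100 * sum(isl$n_defense) / sum(isl$span_genes))

  one <- data.frame(span_genes = 10L, n_defense = 5L)
  expect_equal(island_census(one)$defense_gene_pct, 50.0)
  empty <- island_census(isl[0, ])
  expect_equal(empty$n_islands, 0)
  expect_true(is.na(empty$defense_gene_pct))
})

test_that("island family composition partitions island systems into shares", {
  g <- toy_genome(100, def_idx = 10:15,
                  def_fam = c("RM", "CBASS", "Wadjet", "RM", "Septu", "CBASS"))
  isl <- detect_islands(g)
  comp <- island_family_composition(isl, g$systems, first_line = FIRST_LINE)
  expect_equal(comp$first_line_share + comp$accessory_share, 1)
  expect_equal(comp$first_line_share, 2 / 6)
  comp2 <- island_family_composition(isl, g$systems, first_line = character(0))
  expect_equal(comp2$first_line_share, 0)
  expect_equal(comp2$accessory_share, 1)
  expect_error(island_family_composition(isl[0, ], g$systems, FIRST_LINE),
               "no systems")
})
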
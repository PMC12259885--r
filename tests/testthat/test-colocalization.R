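mge_row <- function(contig, start, end, cls, gid = "g1") {
  data.frame(mge_id = sprintf("%s:%d-%d:%s", contig, start, end, cls),
             genome_id = gid, contig_id = contig, start = start, end = end,
             mge_class = cls, stringsAsFactors = FALSE)
}

test_that("compartment assignment requires every gene midpoint inside one interval", {
  # two-gene system (indices 24, 25), prophage covering genes 20..29
  pro <- mge_row("g1_c1", 20001L, 30000L, "phage_prophage")
  g <- toy_genome(100, def_idx = c(24, 25), def_fam = c("RM", "RM"),
                  mges = pro)
  sys2 <- g$systems[1, ]
  sys2$gene_ids <- paste(g$genes$gene_id[g$genes$index %in% c(24, 25)],
                         collapse = ",")
  got <- assign_compartments(sys2, g$genes, g$mges)
  expect_equal(got$compartment, "phage_prophage")

  # no MGEs at all -> chromosome
  g0 <- toy_genome(100, def_idx = c(24, 25), def_fam = c("RM", "RM"))
  expect_true(all(assign_compartments(g0$systems, g0$genes,
                                      g0$mges)$compartment == "chromosome"))

  # one gene outside the interval -> chromosome under the all-genes rule,
  # MGE under the majority rule only when > half the genes are inside
  sys3 <- sys2
  sys3$gene_ids <- paste(g$genes$gene_id[g$genes$index %in% c(28, 29, 30)],
                         collapse = ",")
  expect_equal(assign_compartments(sys3, g$genes, g$mges)$compartment,
               "chromosome")
  expect_equal(assign_compartments(sys3, g$genes, g$mges,
                                   containment = "majority")$compartment,
               "phage_prophage")
})

test_that("overlapping MGE calls resolve by priority; disjoint calls ignore it", {
  pla <- mge_row("g1_c1", 10001L, 60000L, "plasmid")
  intg <- mge_row("g1_c1", 20001L, 30000L, "integron")
  g <- toy_genome(100, def_idx = c(24, 25), def_fam = c("RM", "RM"),
                  mges = rbind(pla, intg))
  sys <- g$systems[1, ]
  sys$gene_ids <- paste(g$genes$gene_id[g$genes$index %in% c(24, 25)],
                        collapse = ",")
  expect_equal(assign_compartments(sys, g$genes, g$mges)$compartment,
               "integron")
  expect_equal(assign_compartments(sys, g$genes, g$mges,
                                   priority = c("plasmid", "integron",
                                                "phage_prophage",
                                                "ice_ime"))$compartment,
               "plasmid")
  # non-overlapping annotation: assignment independent of priority order
  g2 <- toy_genome(100, def_idx = c(24, 25), def_fam = c("RM", "RM"),
                   mges = rbind(mge_row("g1_c1", 20001L, 30000L, "plasmid"),
                                mge_row("g1_c1", 50001L, 60000L, "integron")))
  sys2 <- g2$systems[1, ]
  sys2$gene_ids <- paste(g2$genes$gene_id[g2$genes$index %in% c(24, 25)],
                         collapse = ",")
  for (pr in list(c("ice_ime", "integron", "phage_prophage", "plasmid"),
                  c("plasmid", "phage_prophage", "integron", "ice_ime")))
    expect_equal(assign_compartments(sys2, g2$genes, g2$mges,
                                     priority = pr)$compartment, "plasmid")
})

test_that("O/E cells follow total_f x total_c / N with the 2x2 chi-square", {
  fam <- c(rep("A", 20), rep("B", 80))
  comp <- c(rep("plasmid", 10), rep("chromosome", 10), rep("chromosome", 80))
  oe <- oe_table(fam, comp)
  cell <- oe[oe$family == "A" & oe$compartment == "plasmid", ]
  expect_equal(cell$expected, 2.0)
  expect_equal(cell$ratio, 5.0)
  # Yates-corrected chi-square of [[10,10],[0,80]]:
  # sum (|O-E| - 0.5)^2 / E over the four cells = 39.0625
  expect_equal(cell$chi2, 39.0625, tolerance = 1e-9)
  expect_lt(cell$p, 1e-8)

  # margins of E match margins of O exactly
  for (f in c("A", "B"))
    expect_equal(sum(oe$expected[oe$family == f]),
                 sum(oe$observed[oe$family == f]), tolerance = 1e-9)
  for (cc in unique(comp))
    expect_equal(sum(oe$expected[oe$compartment == cc]),
                 sum(oe$observed[oe$compartment == cc]), tolerance = 1e-9)

  # counts constructed independent of compartment -> every ratio is 1
  fam2 <- rep(c("A", "B"), times = c(40, 60))
  comp2 <- c(rep(c("chromosome", "plasmid"), times = c(30, 10)),
             rep(c("chromosome", "plasmid"), times = c(45, 15)))
  oe2 <- oe_table(fam2, comp2)
  expect_true(all(abs(oe2$ratio - 1) < 1e-12))
  expect_error(oe_table(character(0), character(0)), "zero systems")
})

test_that("shuffling compartment labels brackets O/E around 1", {
  set.seed(71)
  fam <- rep(c("A", "B", "C"), times = c(60, 40, 20))
  comp <- sample(rep(c("chromosome", "plasmid"), times = c(90, 30)))
  for (f in c("A", "B", "C")) {
    ratios <- replicate(1000, {
      sh <- sample(comp)
      o <- sum(fam == f & sh == "plasmid")
      e <- sum(fam == f) * sum(sh == "plasmid") / length(fam)
      o / e
    })
    qs <- stats::quantile(ratios, c(0.025, 0.975))
    expect_lte(qs[[1]], 1)
    expect_gte(qs[[2]], 1)
  }
})

test_that("compartment densities are systems per kb of compartment length", {
  # one 2-gene system on a 10 kb plasmid within a 100 kb genome
  pla <- mge_row("g1_c1", 20001L, 30000L, "plasmid")
  g <- toy_genome(100, def_idx = c(24, 25), def_fam = c("RM", "RM"),
                  mges = pla)
  sys <- g$systems[1, ]
  sys$gene_ids <- paste(g$genes$gene_id[g$genes$index %in% c(24, 25)],
                        collapse = ",")
  sysc <- assign_compartments(sys, g$genes, g$mges)
  dens <- compartment_density(sysc, g$mges, g$qc)
  expect_equal(dens$density_per_kb[dens$compartment == "plasmid"], 0.1)
  expect_equal(dens$total_bp[dens$compartment == "chromosome"], 90000)
  expect_equal(dens$density_per_kb[dens$compartment == "chromosome"], 0)

  g0 <- toy_genome(100, mges = pla)
  d0 <- compartment_density(assign_compartments(g0$systems, g0$genes, g0$mges),
                            g0$mges, g0$qc)
  expect_true(all(d0$density_per_kb == 0))
})

test_that("the planted MGE density multiplier is recovered from simulations", {
  ratios <- sapply(81:85, function(s) {
    p <- cohort_params(n_genomes = 120,
                       genome_size = list(meanlog = log(5e5), sdlog = 0.3),
                       island_spec = list(n_islands = 0,
                                          genes_per_island = c(5, 9),
                                          gap_range = c(0, 3),
                                          families_per_island = c(3, 5),
                                          n_near_miss = 0),
                       mge_spec = list(
                         rates = c(plasmid = 5.9, phage_prophage = 1.46,
                                   integron = 0.098, ice_ime = 0.022),
                         len_range = list(plasmid = c(5000, 40000),
                                          phage_prophage = c(15000, 50000),
                                          integron = c(3000, 10000),
                                          ice_ime = c(20000, 60000)),
                         density_multiplier = 5, accessory_oe = 1),
                       seed = s)
    res <- generate_cohort(p)
    sys <- cohort_systems(res$cohort)
    sysc <- assign_compartments(sys, cohort_genes(res$cohort),
                                cohort_mges(res$cohort))
    dens <- compartment_density(sysc, cohort_mges(res$cohort),
                                cohort_qc(res$cohort))
    mge <- dens[dens$compartment != "chromosome", ]
    (sum(mge$n_systems) / (sum(mge$total_bp) / 1000)) /
      dens$density_per_kb[dens$compartment == "chromosome"]
  })
  expect_lte(abs(stats::median(ratios) - 5), 1)
})
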
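test_that("exact and mismatched protospacers obey the strand and threshold contracts", {
  set.seed(501)
  phage <- c(ph1 = random_dna(600))
  window <- substr(phage[[1]], 101, 136)   # 36-mer

  # identity on the forward strand
  hits <- find_protospacers(c(sp = window), phage)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$phage_start, 101)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$coverage, 1.0)

  # reverse complement: minus strand, forward-strand left-end coordinate
  hits_rc <- find_protospacers(c(sp = oracle_revcomp(window)), phage)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$phage_start, 101)
  expect_equal(hits_rc$strand, "-")

  # one substitution still matches at full coverage; two do not
  ch <- strsplit(window, "")[[1]]
  ch[10] <- setdiff(c("A", "C", "G", "T"), ch[10])[1]
  one_mm <- paste(ch, collapse = "")
  h1 <- find_protospacers(c(sp = one_mm), phage)
  expect_true(any(h1$mismatches == 1 & h1$coverage == 1 &
                  h1$phage_start == 101))
  ch[25] <- setdiff(c("A", "C", "G", "T"), ch[25])[1]
  h2 <- find_protospacers(c(sp = paste(ch, collapse = "")), phage)
  expect_false(any(h2$phage_start == 101 & h2$mismatches <= 1))

  # N never matches, in either sequence
  chN <- strsplit(window, "")[[1]]; chN[c(5, 20)] <- "N"
  expect_equal(nrow(find_protospacers(c(sp = paste(chN, collapse = "")),
                                      phage)), 0)
  expect_error(find_protospacers(c(sp = ""), phage), "empty")
})

test_that("the optimized matcher equals the brute-force window scanner", {
  set.seed(502)
  for (case in seq_len(80)) {
    plen <- sample(250:500, 1)
    phage <- setNames(random_dna(plen), "ph")
    L <- sample(25:45, 1)
    sp <- if (runif(1) < 0.7) {
      # seed from a real window, then mutate 0-3 positions
      pos <- sample(plen - L + 1, 1)
      w <- substr(phage, pos, pos + L - 1)
      nmut <- sample(0:3, 1)
      ch <- strsplit(w, "")[[1]]
      if (nmut) for (p in sample(L, nmut))
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      if (runif(1) < 0.5) paste(ch, collapse = "")
      else oracle_revcomp(paste(ch, collapse = ""))
    } else random_dna(L)
    got <- find_protospacers(c(q = sp), phage)
    want <- oracle_protospacers(sp, "q", phage)
    expect_equal(got, want)
  }
})

test_that("matching a reverse-complemented phage swaps strands and maps coordinates", {
  set.seed(503)
  phage <- c(ph = random_dna(400))
  spacers <- setNames(lapply(1:6, function(i) {
    pos <- sample(360, 1)
    w <- substr(phage[[1]], pos, pos + 35)
    if (i %% 2) w else oracle_revcomp(w)
  }), paste0("s", 1:6))
  spacers <- unlist(spacers)
  fwd <- find_protospacers(spacers, phage)
  rev <- find_protospacers(spacers, c(ph = oracle_revcomp(phage[[1]])))
  expect_equal(nrow(fwd), nrow(rev))
  len <- nchar(phage[[1]])
  mapped <- data.frame(
    spacer_id = rev$spacer_id,
    phage_start = len - (rev$phage_start + rev$aligned_len) + 2L,
    strand = ifelse(rev$strand == "+", "-", "+"),
    aligned_len = rev$aligned_len, mismatches = rev$mismatches,
    stringsAsFactors = FALSE)
  o1 <- fwd[order(fwd$spacer_id, fwd$phage_start),
            c("spacer_id", "phage_start", "strand", "aligned_len",
              "mismatches")]
  o2 <- mapped[order(mapped$spacer_id, mapped$phage_start), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("host links aggregate hits to distinct host-phage pairs", {
  hits <- data.frame(
    spacer_id = c("a", "a", "b", "c"),
    phage_id = c("p1", "p1", "p1", "p2"),
    phage_start = c(1L, 50L, 9L, 4L), strand = "+",
    aligned_len = 36L, mismatches = 0L, coverage = 1, identity = 1,
    stringsAsFactors = FALSE)
  origin <- c(a = "host1", b = "host1", c = "host2")
  links <- link_hosts(hits, origin)
  expect_equal(nrow(links), 2)
  expect_equal(links$n_hits[links$host_genome == "host1"], 3)
  expect_equal(attr(links, "n_phages_targeted"), 2)
  expect_error(link_hosts(hits, origin[-1]), "without a recorded host")
  empty <- link_hosts(hits[0, ], origin)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_phages_targeted"), 0)
})

anti_gene <- function(phage, idx, type) {
  data.frame(genome_id = phage, contig_id = phage,
             gene_id = sprintf("%s_g%03d", phage, idx), index = idx,
             start = 1L + idx * 1000L, end = idx * 1000L + 900L, strand = "+",
             labels = if (is.na(type)) NA_character_
                      else paste0("anti_defense:", type),
             stringsAsFactors = FALSE)
}

test_that("anti-defense tallies count genes, types and carrier prevalence", {
  genes <- rbind(anti_gene("p1", 1, "Acr"), anti_gene("p1", 5, "anti-RM"),
                 anti_gene("p2", 2, "Acr"), anti_gene("p2", 3, NA),
                 anti_gene("p3", 1, NA))
  tl <- tally_anti_defense(genes, phage_universe_size = 100)
  expect_equal(tl$n_genes, 3)
  expect_equal(tl$per_type[["Acr"]], 2)
  expect_equal(tl$n_phages, 2)
  expect_equal(tl$prevalence_pct, 2.0)
  expect_equal(sum(tl$per_type), tl$n_genes)
  expect_error(tally_anti_defense(genes, phage_universe_size = 1),
               "smaller")
  t0 <- tally_anti_defense(anti_gene("p9", 1, NA), 50)
  expect_equal(t0$n_genes, 0)
  expect_equal(t0$prevalence_pct, 0.0)
})

test_that("co-localized anti-defense reporting keeps only multi-carrier phages", {
  genes <- rbind(anti_gene("p1", 3, "anti-RM"), anti_gene("p1", 1, "Acr"),
                 anti_gene("p2", 2, "Acr"),
                 anti_gene("p3", 1, "Acr"), anti_gene("p3", 2, "anti-CBASS"),
                 anti_gene("p3", 7, "anti-Thoeris"))
  co <- colocalized_anti_defense(genes)
  expect_equal(co$phage_id, c("p3", "p1"))
  expect_equal(co$context[co$phage_id == "p1"], "Acr,anti-RM") # gene order
  expect_equal(co$n_anti_genes, c(3L, 2L))
})

test_that("novelty classification applies the coverage-and-identity rule", {
  hits <- data.frame(query = c("q1", "q2", "q2", "q3"),
                     coverage = c(0.95, 0.85, 0.70, 0.85),
                     identity = c(0.95, 0.85, 0.99, 0.95),
                     stringsAsFactors = FALSE)
  got <- novelty_classify(hits, queries = c("q1", "q2", "q3", "q4"))
  expect_equal(got$status, c("known", "novel", "known", "novel"))
  got_or <- novelty_classify(hits, queries = c("q1", "q2", "q3", "q4"),
                             rule = "or")
  expect_equal(got_or$status, c("known", "known", "known", "novel"))
  expect_error(novelty_classify(data.frame(query = "q", coverage = 80,
                                           identity = 0.9)), "fractions")
})
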
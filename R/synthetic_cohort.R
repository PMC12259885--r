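#' @importFrom stats rlnorm rnbinom rpois runif rnorm setNames
NULL

# run code under a temporary RNG state, restoring the caller's stream
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Default defense-family pool
#'
#' Five dominant families (R-M, SoFIC, CRISPR-Cas, AbiE, MazEF) followed by a
#' long tail of accessory families, with Zipf-decaying prevalence weights
#' (weight of the i-th family proportional to i^-exponent). The decay
#' exponent 1.3 over 30 families puts roughly 70% of all systems in the top
#' five families, matching the few-dominant / many-rare structure typical of
#' environmental defensome surveys.
#'
#' @param n_accessory number of accessory families (max 25).
#' @param zipf_exponent decay exponent of the rank-weight law.
#' @return data frame with columns `family`, `weight`, `first_line`.
#' @export
default_family_pool <- function(n_accessory = 25, zipf_exponent = 1.3) {
  first_line <- c("RM", "SoFIC", "CRISPR-Cas", "AbiE", "MazEF")
  accessory <- c("CBASS", "Wadjet", "Septu", "Gabija", "Thoeris", "Hachiman",
                 "Lamassu", "Zorya", "Druantia", "BstA", "dGTPase", "PARIS",
                 "Retron", "DarTG", "Mokosh", "AVAST", "Shedu", "Kiwa",
                 "RosmerTA", "PD-T4-2", "Nhi", "PrrC", "Borvo", "Dodola",
                 "Olokun")
  stopifnot(n_accessory >= 1, n_accessory <= length(accessory))
  fam <- c(first_line, accessory[seq_len(n_accessory)])
  w <- seq_along(fam)^(-zipf_exponent)
  data.frame(family = fam, weight = w / sum(w),
             first_line = fam %in% first_line, stringsAsFactors = FALSE)
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the annotated-genome inputs of a groundwater-style MAG
#' survey: log-normal genome sizes around 2.5 Mbp, one gene per kbp (900 bp
#' genes with 100 bp spacers), a Zipf family pool, a mean of 3.2 defense
#' systems per genome with strong overdispersion (NB size 0.8, which yields
#' about 28% defense-free genomes and about 1% with more than 20 systems),
#' per-genome MGE rates matching a cohort with ~5.9 plasmids, ~1.5
#' phages/prophages, ~0.1 integrons and ~0.02 ICE/IMEs per genome, and one
#' planted defense island per ~40 genomes. Enrichment multipliers are target
#' observed/expected ratios (see the methods vignette).
#'
#' @param n_genomes number of genomes.
#' @param genome_size list with `meanlog`, `sdlog` of the log-normal size (bp).
#' @param family_pool data frame as from [default_family_pool()].
#' @param mean_systems mean dispersed defense systems per genome (scales with
#'   genome size).
#' @param systems_dispersion negative-binomial `size` parameter.
#' @param island_spec list: `n_islands` (cohort-wide), `genes_per_island`
#'   (range of defense genes per island), `gap_range` (intervening non-defense
#'   genes between consecutive island defense genes), `families_per_island`
#'   (range), `n_near_miss` (clusters deliberately violating exactly one rule).
#' @param mge_spec list: per-class `rates` (expected intervals per genome),
#'   per-class `len_range` (bp), `density_multiplier` (target MGE:chromosome
#'   defense-density ratio), `accessory_oe` (target O/E of accessory families
#'   on MGEs).
#' @param island_accessory_oe target O/E of accessory families in islands.
#' @param tradeoff named list of `c(a, b, c)` logistic-ceiling parameters per
#'   trait; a genome with x systems draws its trait count uniformly from
#'   0..round(a / (1 + exp(b * (x - c)))).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_genomes = 500,
                          genome_size = list(meanlog = log(2.5e6), sdlog = 0.35),
                          family_pool = default_family_pool(),
                          mean_systems = 3.2,
                          systems_dispersion = 0.8,
                          island_spec = list(n_islands = 12,
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
                            density_multiplier = 3,
                            accessory_oe = 3),
                          island_accessory_oe = 3,
                          tradeoff = list(ARG = c(a = 40, b = 0.5, c = 10),
                                          MRG = c(a = 25, b = 0.5, c = 10),
                                          VFG = c(a = 15, b = 0.4, c = 8)),
                          seed = 1L) {
  stopifnot(n_genomes >= 0, mean_systems > 0, systems_dispersion > 0,
            all(mge_spec$rates >= 0), island_spec$n_islands >= 0,
            island_spec$gap_range[1] >= 0, island_spec$gap_range[2] <= 10,
            island_spec$genes_per_island[1] >= 5,
            island_spec$families_per_island[1] >= 3,
            mge_spec$density_multiplier >= 0, mge_spec$accessory_oe >= 0,
            island_accessory_oe >= 0)
  structure(list(n_genomes = as.integer(n_genomes), genome_size = genome_size,
                 family_pool = family_pool, mean_systems = mean_systems,
                 systems_dispersion = systems_dispersion,
                 island_spec = island_spec, mge_spec = mge_spec,
                 island_accessory_oe = island_accessory_oe,
                 tradeoff = tradeoff, seed = as.integer(seed)),
            class = "cohort_params")
}

# minimum index separation between independent defense placements: 12 slots
# leaves >= 11 intervening genes, which can never be chained at max_gap = 10.
.DEF_MARGIN <- 12L

# place a run of k consecutive gene slots on one contig state, drawing
# uniformly from the exact set of valid start slots (NA iff none exists).
# region: "chr" (outside every MGE) or an MGE row index. A placement must
# keep .DEF_MARGIN slots away from every defense gene already on the contig.
.place_run <- function(st, k, region = "chr", tries = NULL) {
  m <- st$m
  if (identical(region, "chr")) {
    lo <- 0L; hi <- m - k
  } else {
    lo <- st$mges$u[region]; hi <- st$mges$v[region] - k + 1L
  }
  if (hi < lo) return(NA_integer_)
  ok <- rep(TRUE, hi - lo + 1L)   # position i <-> start slot u = lo + i - 1
  if (identical(region, "chr") && nrow(st$mges)) {
    for (j in seq_len(nrow(st$mges))) {
      a <- max(lo, st$mges$u[j] - k + 1L); b <- min(hi, st$mges$v[j])
      if (a <= b) ok[(a - lo + 1L):(b - lo + 1L)] <- FALSE
    }
  }
  for (d in st$def) {
    a <- max(lo, d - (.DEF_MARGIN - 1L) - (k - 1L))
    b <- min(hi, d + (.DEF_MARGIN - 1L))
    if (a <= b) ok[(a - lo + 1L):(b - lo + 1L)] <- FALSE
  }
  cand <- which(ok)
  if (!length(cand)) return(NA_integer_)
  lo + (if (length(cand) == 1L) cand else sample(cand, 1L)) - 1L
}

# compose one island: system sizes (1-2 genes), families, intra-island gaps
.compose_island <- function(spec, pool, p_acc, n_def_override = NULL) {
  n_def <- if (!is.null(n_def_override)) n_def_override
    else sample(seq(spec$genes_per_island[1], spec$genes_per_island[2]), 1L)
  sizes <- integer(0)
  left <- n_def
  while (left > 0L) {
    s <- min(left, sample(1:2, 1L))
    sizes <- c(sizes, s); left <- left - s
  }
  n_sys <- length(sizes)
  fr <- spec$families_per_island
  n_fam <- min(sample(seq(fr[1], fr[2]), 1L), n_sys)
  s_acc <- sum(pool$weight[!pool$first_line])
  w <- pool$weight * ifelse(pool$first_line, (1 - p_acc) / (1 - s_acc),
                            p_acc / s_acc)
  fams <- sample(pool$family, n_fam, prob = w)
  fam_of_sys <- c(fams, if (n_sys > n_fam)
    sample(fams, n_sys - n_fam, replace = TRUE))
  gaps <- if (n_def > 1L)
    sample(seq(spec$gap_range[1], spec$gap_range[2]), n_def - 1L,
           replace = TRUE) else integer(0)
  list(n_def = n_def, sizes = sizes, families = fam_of_sys, gaps = gaps)
}

.generate_genome <- function(gid, gseed, size_bp, n_islands, n_near_miss,
                             params) {
  set.seed(gseed)
  pool <- params$family_pool
  s_acc <- sum(pool$weight[!pool$first_line])
  n_slots <- max(60L, as.integer(round(size_bp / 1000)))
  size_bp <- n_slots * 1000L

  # contigs
  n_ctg <- if (n_slots < 150L) 1L else sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
  base <- 40L
  extra <- as.vector(stats::rmultinom(1, n_slots - base * n_ctg,
                                      rep(1, n_ctg)))
  ctg_slots <- base + extra
  ctg_names <- sprintf("%s_c%d", gid, seq_len(n_ctg))
  states <- lapply(ctg_slots, function(m)
    list(m = m, mges = data.frame(u = integer(0), v = integer(0),
                                  class = character(0),
                                  stringsAsFactors = FALSE),
         def = integer(0)))
  names(states) <- ctg_names

  sys_rows <- list()    # (family, contig, slots, island_id)
  islands_truth <- list()
  near_truth <- list()
  sys_counter <- 0L
  add_system <- function(family, contig, slots) {
    sys_counter <<- sys_counter + 1L
    sys_rows[[sys_counter]] <<- list(family = family, contig = contig,
                                     slots = slots)
    sys_counter
  }

  # planted islands go first, on clean contigs, so they always find room;
  # MGE intervals may later overlap them (as real prophage-borne islands do)
  plant_cluster <- function(comp) {
    span <- comp$n_def + sum(comp$gaps)
    ord <- order(ctg_slots, decreasing = TRUE)
    for (ct in ord) {
      st <- states[[ct]]
      u <- .place_run(st, span, "chr")
      if (!is.na(u)) {
        def_slots <- u + cumsum(c(0L, comp$gaps + 1L))
        st$def <- c(st$def, def_slots)
        states[[ct]] <<- st
        sys_ids <- integer(0)
        pos <- 1L
        for (j in seq_along(comp$sizes)) {
          sl <- def_slots[pos:(pos + comp$sizes[j] - 1L)]
          sys_ids <- c(sys_ids, add_system(comp$families[j], ctg_names[ct], sl))
          pos <- pos + comp$sizes[j]
        }
        return(list(contig = ctg_names[ct], first = u,
                    last = def_slots[comp$n_def], sys = sys_ids))
      }
    }
    NULL
  }
  p_acc_isl <- min(0.95, params$island_accessory_oe * s_acc)
  for (i in seq_len(n_islands)) {
    comp <- .compose_island(params$island_spec, pool, p_acc_isl)
    res <- plant_cluster(comp)
    if (is.null(res))
      stop("island specification infeasible: no contig of genome ", gid,
           " can host a ", comp$n_def + sum(comp$gaps), "-gene span")
    islands_truth[[length(islands_truth) + 1L]] <- data.frame(
      genome_id = gid, contig_id = res$contig, first_index = res$first,
      last_index = res$last, n_defense = comp$n_def,
      families = paste(sort(unique(comp$families)), collapse = ","),
      system_ids = NA_character_, sys_idx = I(list(res$sys)),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_near_miss)) {
    # violates exactly the minimum-defense-gene rule (4 genes, >= 3 families)
    comp <- .compose_island(params$island_spec, pool, p_acc_isl,
                            n_def_override = 4L)
    res <- plant_cluster(comp)
    if (is.null(res)) next
    near_truth[[length(near_truth) + 1L]] <- data.frame(
      genome_id = gid, contig_id = res$contig, first_index = res$first,
      last_index = res$last, n_defense = comp$n_def,
      reason = "min_def_genes", stringsAsFactors = FALSE)
  }

  # MGE intervals, aligned to gene slots, non-overlapping
  for (cls in names(params$mge_spec$rates)) {
    n_c <- rpois(1L, params$mge_spec$rates[[cls]])
    if (n_c == 0L) next
    rng <- params$mge_spec$len_range[[cls]]
    for (i in seq_len(n_c)) {
      k <- max(2L, as.integer(round(runif(1, rng[1], rng[2]) / 1000)))
      fit <- which(ctg_slots >= k + 4L)
      if (!length(fit)) next
      ct <- if (length(fit) == 1L) fit else
        sample(fit, 1L, prob = ctg_slots[fit])
      st <- states[[ct]]
      placed <- NA_integer_
      for (t in seq_len(50L)) {
        u <- sample.int(st$m - k + 1L, 1L) - 1L
        v <- u + k - 1L
        if (nrow(st$mges) && any(st$mges$u <= v & st$mges$v >= u)) next
        placed <- u; break
      }
      if (is.na(placed)) next
      st$mges <- rbind(st$mges,
                       data.frame(u = placed, v = placed + k - 1L, class = cls,
                                  stringsAsFactors = FALSE))
      states[[ct]] <- st
    }
  }

  # dispersed systems, MGE-resident with probability targeting the planted
  # density multiplier and accessory O/E
  mge_slots <- sum(vapply(states, function(st)
    sum(st$mges$v - st$mges$u + 1L), integer(1)))
  phi <- mge_slots / n_slots
  d <- params$mge_spec$density_multiplier
  rho <- if (phi > 0) d * phi / (1 - phi + d * phi) else 0
  oe_m <- params$mge_spec$accessory_oe
  p_res_acc <- min(1, oe_m * rho)
  p_res_fl <- if (s_acc < 1) max(0, rho * (1 - oe_m * s_acc) / (1 - s_acc))
              else rho
  exp_size <- exp(params$genome_size$meanlog + params$genome_size$sdlog^2 / 2)
  # MGE-borne systems are additive load on top of the chromosomal baseline:
  # scaling the count mean by 1 + (d - 1) * phi keeps the pooled
  # MGE:chromosome density ratio at the planted multiplier even when MGE
  # content varies between genomes. The cohort-expected MGE fraction
  # normalises the overall mean back to mean_systems.
  exp_phi <- sum(vapply(names(params$mge_spec$rates), function(cl)
    params$mge_spec$rates[[cl]] * mean(params$mge_spec$len_range[[cl]]),
    numeric(1))) / exp_size
  base_mu <- params$mean_systems / (1 + (d - 1) * min(exp_phi, 0.9))
  mu <- base_mu * (size_bp / exp_size) * (1 + (d - 1) * phi)
  n_sys <- rnbinom(1L, size = params$systems_dispersion, mu = mu)
  if (n_sys > 0L) {
    fams <- sample(pool$family, n_sys, replace = TRUE, prob = pool$weight)
    accs <- fams %in% pool$family[!pool$first_line]
    szs <- sample(1:3, n_sys, replace = TRUE, prob = c(0.55, 0.30, 0.15))
    res_p <- ifelse(accs, p_res_acc, p_res_fl)
    resident <- runif(n_sys) < res_p
    for (i in seq_len(n_sys)) {
      k <- szs[i]
      placed <- FALSE
      if (resident[i]) {
        # try MGEs in length-weighted random order until one has room
        cand <- do.call(rbind, lapply(seq_along(states), function(ct) {
          mg <- states[[ct]]$mges
          if (!nrow(mg)) return(NULL)
          data.frame(ct = ct, row = seq_len(nrow(mg)),
                     len = mg$v - mg$u + 1L)
        }))
        if (!is.null(cand) && nrow(cand)) {
          ord <- if (nrow(cand) == 1L) 1L else
            sample.int(nrow(cand), prob = cand$len)
          for (pick in ord) {
            ct <- cand$ct[pick]
            u <- .place_run(states[[ct]], k, region = cand$row[pick],
                            tries = 50L)
            if (!is.na(u)) {
              states[[ct]]$def <- c(states[[ct]]$def, u:(u + k - 1L))
              add_system(fams[i], ctg_names[ct], u:(u + k - 1L))
              placed <- TRUE
              break
            }
          }
        }
      }
      if (!placed) {
        ord <- sample(seq_along(states))
        for (ct in ord) {
          u <- .place_run(states[[ct]], k, "chr")
          if (!is.na(u)) {
            states[[ct]]$def <- c(states[[ct]]$def, u:(u + k - 1L))
            add_system(fams[i], ctg_names[ct], u:(u + k - 1L))
            placed <- TRUE
            break
          }
        }
      }
      # systems that find no room anywhere are dropped
    }
  }

  # materialise tables
  genes <- do.call(rbind, lapply(seq_along(states), function(ct) {
    m <- states[[ct]]$m
    idx <- seq_len(m) - 1L
    data.frame(genome_id = gid, contig_id = ctg_names[ct],
               gene_id = sprintf("%s_g%05d", ctg_names[ct], idx),
               index = idx, start = 1L + idx * 1000L,
               end = idx * 1000L + 900L,
               strand = sample(c("+", "-"), m, replace = TRUE),
               labels = NA_character_, stringsAsFactors = FALSE)
  }))
  effector_pool <- c("nucleic-acid-degrading", "abortive", "unknown")
  systems <- if (sys_counter) do.call(rbind, lapply(seq_len(sys_counter),
    function(i) {
      r <- sys_rows[[i]]
      data.frame(system_id = sprintf("%s_s%04d", gid, i), genome_id = gid,
                 family = r$family, subtype = NA_character_,
                 effector_type = sample(effector_pool, 1L,
                                        prob = c(0.56, 0.07, 0.37)),
                 gene_ids = paste(sprintf("%s_g%05d", r$contig, r$slots),
                                  collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    else data.frame(system_id = character(0), genome_id = character(0),
                    family = character(0), subtype = character(0),
                    effector_type = character(0), gene_ids = character(0),
                    stringsAsFactors = FALSE)
  mges <- do.call(rbind, lapply(seq_along(states), function(ct) {
    mg <- states[[ct]]$mges
    if (!nrow(mg)) return(NULL)
    start <- 1L + mg$u * 1000L
    end <- (mg$v + 1L) * 1000L
    data.frame(mge_id = sprintf("%s:%d-%d:%s", ctg_names[ct], start, end,
                                mg$class),
               genome_id = gid, contig_id = ctg_names[ct], start = start,
               end = end, mge_class = mg$class, stringsAsFactors = FALSE)
  }))
  if (is.null(mges))
    mges <- data.frame(mge_id = character(0), genome_id = character(0),
                       contig_id = character(0), start = integer(0),
                       end = integer(0), mge_class = character(0),
                       stringsAsFactors = FALSE)

  x <- nrow(systems)
  traits <- vapply(params$tradeoff, function(p) {
    cap <- as.integer(round(p[["a"]] / (1 + exp(p[["b"]] * (x - p[["c"]])))))
    sample.int(cap + 1L, 1L) - 1L
  }, integer(1))
  qc <- data.frame(
    genome_id = gid, size_bp = size_bp,
    n50_bp = as.integer(round(size_bp / n_ctg)),
    completeness = round(runif(1, 70, 100), 2),
    contamination = round(runif(1, 0, 10), 2),
    domain = "Bacteria",
    phylum = sample(c("Pseudomonadota", "CPR", "Bacteroidota",
                      "Actinomycetota", "Nitrospirota"), 1L,
                    prob = c(0.34, 0.11, 0.20, 0.25, 0.10)),
    class = NA_character_, stringsAsFactors = FALSE)
  vhr <- round(max(0, rnorm(1, 0.5 + 0.05 * x, 0.3)), 3)

  isl <- if (length(islands_truth)) do.call(rbind, islands_truth) else NULL
  if (!is.null(isl)) {
    isl$system_ids <- vapply(isl$sys_idx, function(ix)
      paste(sprintf("%s_s%04d", gid, ix), collapse = ","), character(1))
    isl$sys_idx <- NULL
  }
  list(genome = genome_annotation(qc, genes, systems, mges, traits, vhr),
       islands = isl,
       near = if (length(near_truth)) do.call(rbind, near_truth) else NULL)
}

#' Generate a synthetic annotated-genome cohort with planted ground truth
#'
#' Deterministic given `params$seed`. Each genome gets a gene skeleton
#' (900 bp genes on a 1 kbp grid), MGE intervals, dispersed defense systems
#' (negative-binomial counts scaling with genome size; MGE residency planted
#' to hit the configured density multiplier and accessory O/E), planted
#' defense islands that satisfy the detection rule by construction, optional
#' near-miss clusters that violate exactly one rule, trait counts drawn
#' uniformly below a logistic ceiling of the genome's defense-system count,
#' and QC/VHR records. Dispersed placements keep at least 11 intervening
#' genes away from any other defense gene, so no unplanned island can arise.
#'
#' @param params a [cohort_params()] object.
#' @return list with `cohort` (a `defensome_cohort`) and `truth` (planted
#'   islands, near misses, enrichment multipliers and trade-off parameters).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  empty_truth <- list(
    planted_islands = data.frame(genome_id = character(0),
                                 contig_id = character(0),
                                 first_index = integer(0),
                                 last_index = integer(0),
                                 n_defense = integer(0),
                                 families = character(0),
                                 system_ids = character(0),
                                 stringsAsFactors = FALSE),
    planted_near_misses = data.frame(genome_id = character(0),
                                     contig_id = character(0),
                                     first_index = integer(0),
                                     last_index = integer(0),
                                     n_defense = integer(0),
                                     reason = character(0),
                                     stringsAsFactors = FALSE),
    planted_enrichment = list(
      island_accessory_oe = params$island_accessory_oe,
      mge_accessory_oe = params$mge_spec$accessory_oe,
      mge_density_multiplier = params$mge_spec$density_multiplier),
    tradeoff_params = params$tradeoff,
    seed = params$seed)
  if (params$n_genomes == 0L)
    return(list(cohort = as_cohort(list()), truth = empty_truth))
  .with_seed(params$seed, {
    n <- params$n_genomes
    sizes <- rlnorm(n, params$genome_size$meanlog, params$genome_size$sdlog)
    gseeds <- sample.int(2147483646L, n)
    # size-weighted island host assignment, capped by per-genome capacity so
    # small fragmented genomes are never asked to host more than they can fit
    slots <- pmax(60, round(sizes / 1000))
    capacity <- pmax(1L, slots %/% 80L)
    draw_hosts <- function(k) {
      out <- integer(0)
      cap <- capacity
      for (i in seq_len(k)) {
        open <- which(cap > 0L)
        if (!length(open))
          stop("island specification infeasible: more islands requested ",
               "than the cohort can host")
        h <- if (length(open) == 1L) open else
          sample(open, 1L, prob = sizes[open])
        out <- c(out, h)
        cap[h] <- cap[h] - 1L
      }
      out
    }
    hosts <- if (params$island_spec$n_islands > 0)
      draw_hosts(params$island_spec$n_islands) else integer(0)
    nm <- params$island_spec$n_near_miss
    nm_hosts <- if (!is.null(nm) && nm > 0) draw_hosts(nm) else integer(0)
    isl_per <- tabulate(hosts, nbins = n)
    nm_per <- tabulate(nm_hosts, nbins = n)
    gids <- sprintf("genome_%04d", seq_len(n))
    out <- vector("list", n)
    for (i in seq_len(n))
      out[[i]] <- .generate_genome(gids[i], gseeds[i], sizes[i], isl_per[i],
                                   nm_per[i], params)
    truth <- empty_truth
    isl <- do.call(rbind, Filter(Negate(is.null), lapply(out, `[[`, "islands")))
    if (!is.null(isl)) { rownames(isl) <- NULL; truth$planted_islands <- isl }
    nearm <- do.call(rbind, Filter(Negate(is.null), lapply(out, `[[`, "near")))
    if (!is.null(nearm)) {
      rownames(nearm) <- NULL; truth$planted_near_misses <- nearm
    }
    list(cohort = as_cohort(lapply(out, `[[`, "genome")), truth = truth)
  })
}

#' Generate random phage sequences
#' @param n number of phages.
#' @param len_range length range in bp.
#' @param seed integer seed.
#' @return named character vector of A/C/G/T sequences.
#' @export
generate_phages <- function(n, len_range = c(8000, 30000), seed = 1L) {
  .with_seed(seed, {
    lens <- as.integer(round(runif(n, len_range[1], len_range[2])))
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    setNames(seqs, sprintf("phage_%03d", seq_len(n)))
  })
}

.mutate_seq <- function(s, n_sub, positions = NULL) {
  if (n_sub == 0L) return(s)
  ch <- strsplit(s, "")[[1]]
  if (is.null(positions)) positions <- seq_along(ch)
  pos <- if (length(positions) == 1L) positions
         else sample(positions, n_sub)
  for (p in pos)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate a planted spacer set against a phage collection
#'
#' Positives are copied from phage windows (25-45 bp) with 0 or 1 planted
#' substitutions, on a random strand; negatives are composition-shuffled
#' windows verified (by exhaustive rescan at a relaxed threshold) to sit at
#' least 3 substitutions away from every phage window at >= 90% coverage, so
#' they can never be hit at the default matching thresholds.
#'
#' @param phages named character vector of phage sequences (each >= 60 bp).
#' @param n_pos number of planted protospacer-bearing spacers.
#' @param n_neg number of negative spacers.
#' @param seed integer seed.
#' @param len_range spacer length range.
#' @return list with `spacers` (named character vector) and `truth`
#'   (`planted` data frame: spacer_id, phage_id, position, strand,
#'   n_mismatches; `negatives`: spacer ids).
#' @export
generate_spacer_set <- function(phages, n_pos, n_neg, seed = 1L,
                                len_range = c(25, 45)) {
  stopifnot(length(phages) > 0)
  lens <- nchar(phages)
  if (any(lens < 60)) stop("phage sequences must be at least 60 bp")
  n_windows <- sum(pmax(0L, lens - len_range[1] + 1L))
  if (n_pos > n_windows)
    stop("n_pos exceeds the number of available protospacer windows")
  .with_seed(seed, {
    spacers <- character(0)
    planted <- list()
    for (i in seq_len(n_pos)) {
      L <- sample(seq(len_range[1], len_range[2]), 1L)
      ok <- which(lens >= L)
      ph <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = lens[ok])
      pos <- sample.int(lens[ph] - L + 1L, 1L)
      window <- substr(phages[[ph]], pos, pos + L - 1L)
      n_mm <- sample(0:1, 1L)
      # plant the substitution where every substring alignment of length
      # >= ceiling(0.95 L) must cover it, so the full-length alignment at the
      # planted locus is always the collapse winner and the hit coordinate
      # equals the planted coordinate
      lmin <- as.integer(ceiling(0.95 * L))
      window <- .mutate_seq(window, n_mm, positions = (L - lmin + 1L):lmin)
      strand <- sample(c("+", "-"), 1L)
      sp <- if (strand == "+") window else .revcomp(window)
      id <- sprintf("spacer_%04d", i)
      spacers[id] <- sp
      planted[[i]] <- data.frame(spacer_id = id, phage_id = names(phages)[ph],
                                 position = pos, strand = strand,
                                 n_mismatches = n_mm, stringsAsFactors = FALSE)
    }
    negatives <- character(0)
    for (j in seq_len(n_neg)) {
      id <- sprintf("spacer_%04d", n_pos + j)
      L <- sample(seq(len_range[1], len_range[2]), 1L)
      ph <- sample.int(length(phages), 1L)
      pos <- sample.int(lens[ph] - L + 1L, 1L)
      base <- substr(phages[[ph]], pos, pos + L - 1L)
      sp <- NULL
      for (t in seq_len(50L)) {
        cand <- if (t <= 20L)
          paste(sample(strsplit(base, "")[[1]]), collapse = "")
        else paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
        hits <- find_protospacers(setNames(cand, id), phages, max_mm = 2L,
                                  min_cov = 0.90)
        if (!nrow(hits)) { sp <- cand; break }
      }
      if (is.null(sp))
        stop("could not generate a clean negative spacer after 50 attempts")
      spacers[id] <- sp
      negatives <- c(negatives, id)
    }
    list(spacers = spacers,
         truth = list(planted = if (length(planted)) do.call(rbind, planted)
                        else data.frame(spacer_id = character(0),
                                        phage_id = character(0),
                                        position = integer(0),
                                        strand = character(0),
                                        n_mismatches = integer(0),
                                        stringsAsFactors = FALSE),
                      negatives = negatives))
  })
}
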
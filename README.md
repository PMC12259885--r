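# defensome

Census and comparative analysis of anti-phage defense systems in annotated
prokaryotic genome cohorts.

Prokaryotes defend themselves against phages and other mobile genetic
elements (MGEs) with a large arsenal of defense systems — restriction–
modification, CRISPR–Cas, abortive-infection and toxin–antitoxin modules,
CBASS, and well over a hundred rarer families. Large genome-resolved
surveys (isolate collections or metagenome-assembled genomes) now annotate
these systems at scale, and the interesting biology lives in the
*downstream* statistics: which families dominate, how defense investment
scales with genome size and viral pressure, where systems cluster into
defense islands, how mobile elements carry accessory immunity around, and
what hosts give up (resistance and virulence genes) to afford their
defenses. This package implements that downstream layer for researchers in
microbial ecology and genomics who already have annotations (e.g.
DefenseFinder tables, geNomad/IntegronFinder-style MGE intervals) and want
reproducible, tested cohort-level analysis.

## What it computes

* **Defensome census** — per-genome profiles (system count, density per
  Mbp, family diversity), family prevalence, and the partition into
  *first-line* families (prevalence > 10% of genomes, strict) vs
  *accessory* families; exponential-decline fit of the per-genome count
  distribution; Spearman correlations (average ranks, two-sided
  t-approximation); the high-quality genome filter
  (completeness > 90, contamination < 5, completeness − 5 × contamination
  > 70, N50 > 100 kb, all strict).
* **Defense islands** — maximal chains of defense genes per contig with at
  most 10 intervening non-defense genes between consecutive defense genes,
  kept when they contain ≥ 5 defense genes from ≥ 3 families; island
  census, including the defense-gene proportion 100 · Σ n_def / Σ span.
* **Colocalization enrichment** — assignment of each system to a
  compartment (an MGE class when every member-gene midpoint lies in one
  interval, else chromosome), observed/expected tables with
  E[f,c] = total_f · total_c / N, per-cell 2×2 chi-square (Yates), O/E
  ratios, and per-kb compartment densities. The same machinery contrasts
  island vs non-island systems.
* **Defense/trait trade-off** — the upper envelope y_max(x) of a trait
  count (ARG/MRG/VFG) over the per-genome defense-system count x, fitted
  with the decreasing logistic

  y = a / (1 + e^{b (x − c)}),

  by multi-start Levenberg–Marquardt least squares, evaluated with
  R² = 1 − Σ(y_obs − y_fit)² / Σ(y_obs − ȳ_obs)².
* **Spacer → protospacer matching** — exact ungapped scan of CRISPR spacers
  against phage sequences on both strands at ≤ 1 mismatch and ≥ 95% query
  coverage; virus–host link tables; anti-defense gene tallies and
  co-localization; novelty classification of alignment hits (known iff
  coverage ≥ 80% *and* identity ≥ 90%).
* **Synthetic cohorts** — a seeded generator that plants ground truth for
  every stage (islands that provably satisfy the detection rule,
  enrichment at target O/E ratios, logistic trait ceilings, protospacers
  with controlled mismatches), so the whole pipeline is testable with no
  external data.

## Worked example

The `analysis/` directory holds the numbered drivers of the full analysis
(`01_simulate.R` … `06_spacers.R`), each writing its tables under
`results/`. Running them in order on the built-in synthetic cohort prints:

```
cohort: 300 genomes, 822987 genes, 1035 systems, 2293 MGEs; 0 invariant violations
planted: 8 islands; ARG ceiling a=40 b=0.5 c=10
first-line families (prevalence > 10%): RM, SoFIC, CRISPR-Cas, AbiE, MazEF, CBASS, Wadjet
first-line share of all systems: 75.5%
islands detected: 8 (planted: 8; exact-span recovery: 8/8)
defense genes within islands: 53 of 120 genes (44.2%)
island systems: 31% first-line, 69% accessory
island O/E: accessory 2.83, first-line 0.40
envelope fit: a=39.2 b=0.53 c=9.8 (planted 40/0.5/10), R2=0.994
planted protospacers recovered: 25/25; negatives hit: 0
```

Reading the output: the prevalence rule recovers the dominant families (on
synthetic cohorts the 10% threshold sits near the Zipf tail, so one or two
borderline families can join the canonical five); all eight planted islands
are found with their exact spans; accessory families are enriched in
islands (O/E 2.8) while first-line families are depleted (0.40), the
planted pattern; the logistic ceiling parameters are recovered within a few
percent; and spacer matching finds every planted protospacer while hitting
none of the shuffled negatives.

The same computations are available programmatically:

```r
library(defensome)
res <- generate_cohort(cohort_params(n_genomes = 100, seed = 1))
prev <- prevalence(res$cohort)
part <- partition_first_line(prev)                      # prevalence > 10%
islands <- detect_islands_cohort(res$cohort)            # gap<=10, >=5 genes, >=3 families
oe <- island_oe_table(cohort_systems(res$cohort), islands)
env <- build_envelope(res$cohort, trait = "ARG")
fit <- fit_sigmoid(env, seed = 1)
```

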
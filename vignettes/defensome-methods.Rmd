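---
title: "Defensome analysis: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defensome analysis: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the statistics computed over cohorts of annotated prokaryotic genomes, the
detection and enrichment rules, the trade-off model, the matching criteria,
and the design choices made where more than one reasonable convention
exists. The package operates strictly downstream of annotation: genes,
defense systems (e.g. DefenseFinder output), MGE intervals, QC records and
trait counts are inputs; no HMM scanning, assembly or binning is performed
here.

## The data model

A cohort is a list of `genome_annotation` bundles. Within a genome, genes
carry a 0-based, gap-free `index` per contig — gene order, not physical
coordinates, is the substrate of island detection. Coordinates in all
tabular files are 1-based inclusive (GFF convention); BED input for MGE
intervals is converted from 0-based half-open on read. A *defense gene* is
any gene belonging to at least one `DefenseSystemRecord`; a gene belonging
to two systems is counted once as a defense gene while system membership
stays many-to-many. Family names are opaque, case-sensitive strings: `R-M`
and `RM` are different families unless normalised upstream. Systems are
required to live on a single contig; fragmented systems are flagged by
`validate_cohort()` rather than silently kept, which can undercount
multi-gene systems in very fragmented assemblies.

## Census statistics

`profile_genome()` reports system counts, distinct-family counts and
density in systems per Mbp of *assembly* size. An alternative would be to
normalise by estimated genome size (assembly size divided by completeness);
we use assembly size because completeness estimates carry their own error
and the correlation analyses pair counts with the same assembly-size
covariate.

Family *prevalence* is the fraction of genomes carrying at least one system
of the family. The first-line/accessory partition is a prevalence rule —
families present in strictly more than 10% of genomes are first-line — kept
parameterised rather than hard-coded as a family list, with a named-list
mode (`partition_first_line(prev, named = ...)`) for reproducing a fixed
published partition. On synthetic cohorts the 10% boundary falls near the
6th–7th family of the default pool, so the rule-based partition can include
one or two families beyond the canonical five; this is a property of the
threshold sitting on the flat part of the Zipf tail, not of the rule.

The distribution of per-genome counts is summarised by a least-squares line
through (k, log f_k) over non-empty count bins; zero-frequency bins are
skipped, not imputed, because log 0 is undefined and imputation would bias
the slope. Spearman correlations use average ranks with the two-sided
t-approximation p-value (n − 2 degrees of freedom); for the cohort sizes
involved the difference from the exact permutation null is far below
reporting precision.

The high-quality genome filter is the conjunction of four strict
inequalities: completeness > 90, contamination < 5,
completeness − 5 × contamination > 70, N50 > 100 kb. A genome at
completeness 91 and contamination 4.5 illustrates why the third condition
is not redundant: it passes the first two but fails the penalty bound
(68.5).

## Defense islands

An island is a maximal chain of defense genes on one contig in which
consecutive defense genes are separated by at most `max_gap` intervening
non-defense genes (default 10), retained if it has at least 5 defense genes
from at least 3 distinct families. Two readings of "separated by 10 genes
or less" are possible; we take it as *intervening* genes (index difference
≤ 11) and expose `gap_semantics = "index-diff"` for sensitivity analysis.
"At least five genes" is read as five *defense* genes, since the chain is
defined over defense genes; total span genes are reported separately.
Chains are maximal, so islands can never overlap. Islands never cross
contig ends; in fragmented assemblies this undercounts islands that a
closed genome would join.

One consequence worth noting: the island *count* is not monotone in
`max_gap` — widening the gap can merge two qualifying islands into one.
What is monotone is coverage: every island found at a smaller gap lies
inside an island found at a larger gap, and counts are monotone
non-increasing in the gene and family minima. The tests assert monotonicity
in that form, and verify the detector against an exhaustive enumeration of
maximal qualifying chains on random contigs.

A system counts as "in" an island when at least one member gene lies in the
span (`system_containment = "all"` requires full containment). The census
reports the defense-gene proportion as 100 × (defense genes in islands) /
(island span genes).

## Colocalization and enrichment

A system is assigned to an MGE class only if the midpoint of *every* member
gene lies within a single interval of that class; defense systems are
compact, and partial overlap is ambiguous, so the all-genes rule is the
default with `containment = "majority"` as the alternative. Overlapping MGE
calls (a prophage inside a plasmid contig) are resolved by a fixed priority
— ICE/IME > integron > phage/prophage > plasmid — on the rationale that
smaller, more specific elements outrank larger ones; with non-overlapping
annotations the priority is irrelevant and the tests check exactly that.

Expected counts under independence are E[f, c] = total_f × total_c / N, so
row and column margins of E equal those of O by construction. Each cell is
tested with a chi-square on its 2×2 collapse, Yates-corrected by default
(the default behaviour of `chisq.test` on 2×2 tables), two-sided. Per-cell
p-values are reported raw — the enrichment heat-map convention — with a
Benjamini–Hochberg column alongside for users who want FDR control.
Compartment densities divide system counts by merged compartment lengths;
the chromosomal length is the genome total minus the merged MGE span.

## The trade-off model

The inverse relationship between defense investment and adaptive traits
(ARG/MRG/VFG counts) is modelled on the *upper envelope*: for each distinct
per-genome defense-system count x, the maximum trait count among genomes at
that x. The envelope definition (per-integer-x maximum, optional `min_bin`
filter) is our reconstruction of the published maximum-vs-count panels,
which do not define the envelope formally. The fitted curve is the
decreasing logistic

y = a / (1 + exp(b (x − c))),

symmetric about (c, a/2) with steepness b at the symmetry point, fitted by
least squares on the envelope points. Logistic SSE surfaces have local
minima, so instead of a single `nls` call the fit multi-starts
Levenberg–Marquardt from a deterministic grid (a0 = max y; c0 at the x
quartiles; b0 ∈ {±0.1, ±1}) plus seeded jittered starts, keeping the best
SSE. Envelope points are unweighted by bin size; `n_at_x` is reported so a
weighted variant can be built, but no weighting is applied by default
because none is defined in the source analysis. Fit quality is the plain
residual R² on the envelope points. A flat envelope leaves b unidentifiable
and is reported as `converged = FALSE` rather than an error.

## Spacer–protospacer matching

Matching criteria are ≤ 1 mismatch and ≥ 95% query (spacer) coverage. For
25–45 bp spacers these criteria imply near-full-length ungapped matches, so
the matcher is an exact ungapped scanner — every substring of the spacer of
length ≥ ⌈0.95 L⌉ against every phage window, both strands — rather than a
heuristic local aligner; this is a reimplementation of the filtering
semantics, not a claim of bit-identity with blastn scoring. Coverage is
computed over the query, matching `qcovs` semantics. `N` in either sequence
is a mismatch (conservative under ambiguity). Overlapping alignments of one
spacer at one phage locus (same strand) are collapsed to the single best
hit: fewest mismatches, then longest, then leftmost. Minus-strand hits are
reported at the forward-strand coordinate of the window's left end. The
tests verify the scanner against a character-by-character brute-force
oracle and check the strand involution (matching against
reverse-complemented phages maps coordinates by pos' = len − (pos +
aligned_len) + 2).

The novelty rule classifies a query as *known* only if some hit has both
coverage ≥ 80% and identity ≥ 90% (AND). The source phrasing ("< 80%
coverage and < 90% identity" for novel) is ambiguous between AND and OR for
the novel class; AND-for-known is the stricter novelty call and the
default, with `rule = "or"` implemented for the other reading. Hits are
counted per locus, not deduplicated per spacer–phage pair.

## The synthetic cohort generator

The generator emulates the *structure* of an annotated MAG survey, not its
sequences: 900 bp genes on a 1 kbp grid (island logic depends on gene
order, so physical realism is secondary), log-normal genome sizes around
2.5 Mbp, one to three contigs, and a Zipf-decaying family pool (exponent
1.3 over 30 families) that puts roughly 70% of systems into the five
dominant families. Per-genome system counts are negative binomial with mean
3.2 scaled by genome size and dispersion 0.8 — values chosen to reproduce
the canonical survey picture of ~28% defense-free genomes and ~1% carrying
more than 20 systems. MGE intervals arrive at per-genome class rates of
5.9 / 1.46 / 0.098 / 0.022 (plasmid / phage-prophage / integron / ICE-IME),
the per-MAG averages implied by a large groundwater survey.

Three planting mechanisms carry ground truth:

* **Islands** are composed constructively (system sizes 1–2 genes, ≥ 3
  distinct families, intra-island gaps drawn from 0–3) and placed with at
  least 11 intervening genes between any two independent defense
  placements, so a planted island always passes the detection rule with its
  exact span and nothing else can chain into an unplanned island
  (precision = recall = 1). Near-miss clusters violate exactly one rule
  (4 defense genes) and must not be detected.
* **Enrichment multipliers are target O/E ratios.** A multiplier defined as
  a raw placement-rate ratio would produce O/E = m / ((1 − s) + m s) — about
  1.85 for m = 3 at accessory share s ≈ 0.3 — so the generator instead
  solves for placement probabilities that make the observed/expected ratio
  itself equal the multiplier. MGE residency is additionally modelled as
  additive load: the per-genome count mean scales with 1 + (d − 1)φ (φ =
  MGE genome fraction, d = density multiplier), normalised by the
  cohort-expected φ. Without this, pooling genomes with heterogeneous φ
  attenuates the cohort-level density ratio below the planted value.
* **Trait ceilings**: a genome with x systems draws each trait uniformly
  from 0..round(a / (1 + exp(b(x − c)))), so the per-x envelope maximum
  follows the planted curve up to the discrete uniform maximum gap.
  Planted protospacer substitutions sit in the central spacer positions
  that every qualifying alignment must cover, so the full-length alignment
  at the planted locus always wins the collapse. Negatives are
  composition-shuffled windows re-screened at a relaxed threshold
  (≤ 2 mismatches, ≥ 90% coverage) to guarantee ≥ 3 substitutions from
  every window.

Determinism: one seed per `generate_cohort()` call; genome-level sub-seeds
are drawn up front so the per-genome streams do not reshuffle when cohort
parameters change. All randomness is in R's integer RNG streams.

What the generator does *not* emulate: sequence-level realism (GC skew,
codon usage), phylogenetic structure among genomes, correlated family
co-occurrence, MGE boundary uncertainty, and annotation error. Tests
passing on synthetic cohorts therefore demonstrate the correctness of the
implemented rules and estimators under the stated generative assumptions —
not robustness to mis-annotation in real data.

## Problem sizes and numerical choices

The validation suites run the island detector against an exhaustive oracle
on 1000 random contigs of up to 200 genes, the spacer scanner against brute
force on 500 random instances (phages of 200–450 bp, spacers 25–45 bp),
island-enrichment recovery on ten 150-genome cohorts, and envelope-fit
recovery on 2000-genome cohorts with ~300-gene genomes (the envelope
depends on counts, not genome length, so small genomes keep the cohorts
cheap without changing the planted signal). The multi-start fit uses 16
starts and Levenberg–Marquardt with a 200-iteration cap; expected-count
conservation is checked to 1e-9; O/E cells with E = 0 are reported as NA
rather than infinite.

## Known limitations

Single-contig systems are required rather than inferred across breaks;
islands cannot span contigs; per-cell chi-square tests are reported without
family-wise correction by default; the envelope is sensitive to bin
occupancy at extreme x (a singleton bin's maximum is a single draw), which
is why `min_bin` exists; and the generator's O/E targeting is exact in
expectation but, on small cohorts, realised enrichment varies with the
realised accessory share.
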
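---
title: "Methods: k-mer LCA classification, abundance re-estimation, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer LCA classification, abundance re-estimation, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models and the design
choices behind them: what each component computes, what its tunable
parameters mean, what the synthetic data generator does and does not
emulate, and where the implementation had to commit to a reading that
the underlying method descriptions leave open.

## 1. Taxonomy model

The taxonomy is a rooted, ranked tree built from Greengenes-style
lineage strings (`k__;p__;c__;o__;f__;g__;s__`). Three choices matter:

* **Dense first-encounter ids.** Lineage strings carry no numeric ids,
  so `build_taxonomy()` assigns dense integers in first-encounter order
  with the root at 1. The same input order always produces a
  byte-identical serialized tree, which is what makes index headers
  hashable and database mismatches detectable.
* **Unnamed ranks are skipped, not materialized.** A lineage such as
  `k__B; p__P; c__; g__G` attaches the genus directly to the phylum.
  This mirrors how real 16S lineages degrade and keeps per-rank node
  counts honest — an anonymous class node would inflate the class tally.
  A consequence users should expect: a node's parent may sit several
  canonical ranks above it, and per-read evaluation at a rank excludes
  reads whose true lineage has no node at that rank.
* **Homonyms stay distinct.** Two genera named identically under
  different parents are different nodes (keyed by full lineage), because
  curated 16S taxonomies contain polyphyletic names.

LCA queries compare root-to-node paths; the test suite checks them
against an independent oracle that intersects full ancestor sets and
takes the deepest common element.

Genus-name harmonization across database dialects (hyphen-joined merge
composites, numbered "sensu stricto" split groups) is deliberately a
curated lookup table, not fuzzy matching: the disagreements between the
major 16S taxonomies are editorial, and only curation can say that
`Escherichia-Shigella` should count as `Escherichia`. The packaged
default map covers the well-known merge/split patterns
(`Allorhizobium-Neorhizobium-Pararhizobium-Rhizobium` → `Rhizobium`,
`Escherichia-Shigella` → `Escherichia`, `Clostridium sensu stricto`
1–19 → `Clostridium`); anything larger is user configuration.

## 2. The k-mer → LCA index

Every window of width *k* free of non-ACGT characters contributes its
canonical form (lexicographic minimum of the k-mer and its reverse
complement), and each distinct canonical k-mer is stored under the LCA
of all taxa whose sequences contain it on either strand. Properties the
tests enforce: the map is independent of reference input order, and
adding a reference can only move a k-mer's taxon toward the root, never
deeper.

* **k (default 35).** The classical nucleotide default of the k-mer
  classifier lineage. Larger k means more specific (and fewer shared)
  k-mers; at 35, chance k-mer collisions between unrelated sequences
  are effectively impossible, so every off-species index entry reflects
  genuine shared ancestry in the references. k is fully configurable
  and unit tests use small k (5–11) so brute-force oracles stay cheap.
* **Exact k-mers, plain TSV.** No minimizers, spaced seeds, or
  probabilistic hash tables: classification semantics are defined at
  the k-mer → LCA level, and the serialized index is a sorted
  two-column table (radix/C-locale order, so byte-identical across
  environments) with a header recording k and an MD5 hash of the
  taxonomy it was built against. `classify` refuses to run when index
  and taxonomy hashes disagree.
* **Ambiguity.** IUPAC codes other than ACGT break windows (the window
  is skipped), avoiding combinatorial expansion; such windows count as
  no-hit during classification.

## 3. Per-read classification

All k-mer windows of a read — both mates pooled, for pairs — are looked
up, producing per-taxon hit counts. Each root-to-leaf path of the
hit-induced subtree is scored by the sum of hits on its nodes, and the
read is assigned to the leaf of the maximal path. Numerical/tie choices:

* **Ties resolve to the LCA of all tied leaves.** Equal evidence for
  two species of one genus yields the genus. Because hit counts are
  strictly positive, a hit taxon can never tie with its own hit
  descendant, so tied candidates are always incomparable and the LCA is
  well defined.
* **Every matching window counts equally.** No coverage thresholds or
  confidence scores; the experiments this package models use none.
* **Unclassified reads** (no hit in either mate) get taxon 0 and flag
  `U`; they are exactly the false negatives of the evaluation.

The hierarchical report follows the conventional six-column layout
(percent, clade reads, direct reads, rank code U/R/D/P/C/O/F/G/S, taxon
id, indented name), with the invariant that a node's clade count equals
its direct count plus its children's clade counts.

## 4. Abundance re-estimation

Reads placed at internal ranks make raw target-rank roll-ups
undercount. The redistribution model is estimated by **re-classifying
read-length windows of the reference sequences themselves** (start
positions every `stride` bases): P(n, x) is the fraction of windows
drawn from target-rank taxon *x* that the classifier assigns to node
*n*. Redistribution then:

1. rolls counts at/below the target rank up into their target-rank
   ancestor unchanged;
2. splits a count at a node above the target rank among that node's
   own target-rank descendants proportionally to P(n, ·), renormalized
   within the node's clade;
3. sends counts with no supported descendant (e.g. a family containing
   no genera) to an explicit `unassigned` bucket.

Total reads are conserved exactly, and redistribution is idempotent at
the target rank — both are tested properties. Design choices made here:

* **Single-pass proportional allocation**, not an iterative Bayesian
  update. The re-estimation literature describes the outcome
  (redistribution guided by prior knowledge of the database sequences)
  rather than one canonical iteration scheme; the single-pass rule is
  deterministic, conservative, and testable by hand
  (10 reads at a genus with P = 0.6/0.4 go 6/4).
* **Stride** trades model fidelity for build time: stride 1 classifies
  every window; the test suite and CLI default use larger strides (5–23)
  because at these reference sizes the P estimates are already stable.
* **Integer output** uses largest-remainder rounding so reported
  columns sum exactly to the estimated totals; internal computation
  keeps real-valued counts.

## 5. The synthetic benchmark generator

The generator emulates the structure that makes 16S amplicon
classification work — and hard:

* **Gene layout.** 1,600 bp: a 70-bp conserved block, then nine repeats
  of (100-bp hypervariable block + 70-bp conserved block). Conserved
  blocks are *identical in every reference* (they model universal
  primer landing sites); all divergence happens in the variable blocks.
  Because no conserved run exceeds 70 bp, every 250-bp read overlaps
  hypervariable sequence.
* **Hierarchical divergence.** A random root gene is mutated along the
  generated taxonomy: per-branch substitution rates
  (species 0.02, genus 0.05, family 0.08, phylum 0.15 by default,
  required non-decreasing with taxonomic distance) apply only to
  variable-block positions, so expected pairwise identity is monotone
  in relatedness — a tested property.
* **Primer windows.** V12 [0, 410), V34 [340, 780), V4 [480, 760),
  V45 [480, 920) are fixed presets over this layout (V4 nests inside
  V34, as in the real gene); real primer coordinates are
  database-specific and are not reproduced.
* **Reads.** Mate 1 is the amplicon's 5′ 250 bp; mate 2 the reverse
  complement of its 3′ 250 bp — amplicon sequencing semantics, where
  all fragments share primer-defined ends. Each base substitutes
  independently with probability `mut_rate` (default 0.02) to a
  uniformly chosen different base. **Substitutions only**: indels would
  add an alignment dimension the k-mer model does not engage with, and
  the error process being modeled is stated only as a flat per-base
  mutation rate.
* **Community profiles.** Deterministic log-normal rank-abundance
  curves over genera — steep for gut-like (σ = 1.6), intermediate for
  ocean-like (1.0), flat for soil-like (0.4) — split evenly across each
  genus's species. These are idealized stand-ins for real environment
  compositions, chosen so the three profiles span the dominance
  spectrum a field dataset might show.
* **Not emulated:** PCR chimeras, quality-score structure (FASTQ
  qualities are constant Q40 and never used), indels, copy-number
  variation, contaminant/off-target reads, and reads from taxa absent
  from the database. Passing tests therefore demonstrate correctness of
  the algorithms under the stated error model, not field performance on
  real amplicon data, where database incompleteness dominates error.

## 6. Evaluation metrics

* **MAPE** is computed term-by-term as
  Σ_g (T_g/ΣT) · |A_g − T_g| / T_g over *true* genera only (estimated
  genera absent from the truth contribute nothing directly); a tested
  identity shows this equals Σ_g |A_g − T_g| / ΣT. The statistic can
  exceed 1 when a genus is grossly over-counted; the implementation
  does not clip, and documents this.
* **Bray-Curtis** uses the generalized totals S_i = ΣT, S_j = ΣA so it
  stays defined when the two profiles' totals differ; when totals match
  it reduces to the familiar equal-total form.
* **Per-read confusion.** At evaluation level L: TP = assigned inside
  the true L-taxon's clade (any species of the true genus counts at
  genus level); VP = assigned to a strict ancestor of the true L-taxon
  (correct lineage, less specific); FN = unclassified; FP = everything
  else (off-lineage). The four counts partition the evaluated reads.
  VP is stored *excluding* TP: an inclusive reading would double-count
  TP in the sensitivity denominator, whereas the exclusive reading
  makes Sensitivity = TP/total — consistent with the identity
  TP/(TP+VP+FN+FP) = TP/(TP+VP+FP) when FN = 0. PPV = TP/(TP+FP)
  excludes vague positives from the denominator and is reported as NA
  (not 0) when no read is confidently placed.
* Genus names are harmonized (Section 1) before distribution
  comparisons; multi-sample summaries are unweighted means.

## 7. Problem sizes and benchmark conditions

The package's standard benchmark — used by the acceptance script and
the corresponding tests — is a community of 4 phyla / 12 genera / 24
species at default divergence, 10,000 paired 250-bp reads at 2%
substitution from the V34 window under the gut-like profile, classified
at k = 35 against the index built from the same references. These sizes
keep each experiment in the tens of seconds on a single core while
leaving hundreds of reads on even the rarest genus. On this benchmark,
class- and phylum-level per-read sensitivity and PPV reach 1.0 and no
read is unclassified (every pair retains at least one exact 35-mer with
overwhelming probability: each mate has 216 windows and each retains a
given window intact with probability 0.98^35 ≈ 0.49).

The redistribution-improvement experiment uses a deliberately harder
regime: within-family divergence lowered to 0.002 (genus branches) and
0.001 (species branches) over 20 genera with a flat profile, so that a
read's window frequently carries no sub-family-specific site and a
substantial share of reads (17–56% across the five seeded replicates)
classify above genus. In every replicate, genus-level MAPE after
redistribution is at most that of the raw roll-up, typically several
times smaller.

## 8. Known limitations

* Exact-match k-mers make the classifier brittle to error rates much
  above a few percent with large k; real tools mitigate this with
  minimizer-based matching, which is out of scope here.
* The redistribution model is estimated from the same references the
  index is built from; with real databases, strain-level variation
  absent from the references would bias P.
* The harmonization map is only as good as its curation; no attempt is
  made to resolve genus naming conflicts algorithmically.
* All data structures are in-memory R objects and plain-text files;
  the implementation targets desk-scale studies (up to ~10^5 reads,
  ~10^3 references), not production-scale databases.
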
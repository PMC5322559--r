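---
title: "Mapping selenium utilization traits and nominating candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping selenium utilization traits and nominating candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setraits)
```

## The model

Selenium enters prokaryotic biology through three pathways that all consume
selenophosphate, the product of SelD: selenocysteine decoding
(SelA + SelB + SelD), 2-selenouridine synthesis (SelD + YbbB), and a
putative Se-containing cofactor pathway (SelD + YqeB + YqeC). `setraits`
treats each trait as a pure conjunction over required families evaluated on
a genomes-by-families presence/absence matrix. This is deliberately strict:
partial machineries (say SelA + SelD without SelB) are reported in a
diagnostic table (`partial_traits()`) but never counted, because an
incomplete pathway cannot run. Genomes carrying the shared signature (SelD
under the defaults) but no trait-specific family are flagged orphan-SelD;
the trait-specific set is derived from the definitions themselves
(families not common to all traits), so user-defined traits extend the
orphan rule automatically.

Candidate discovery rests on two complementary signals:

* **Genomic context.** Known Se genes cluster into compact, operon-like
  islands. `find_islands()` builds maximal runs of known-family genes in
  which consecutive Se genes are separated by at most `max_gap` other genes
  (default 3), deterministically left to right. Around every island span, a
  window of `radius` genes (default 10) on each side is unioned per genome;
  any non-excluded family seen inside such a neighborhood is *linked* in
  that genome. Adjacency is ordinal (gene ranks), not base-pair distance,
  because the procedure counts genes, and strand is recorded but ignored.
* **Phylogenetic profile.** A linked family's presence vector is
  cross-tabulated against SelD presence over *all* genomes and tested with
  a 2x2 chi-square. Recurrent linkage plus strong positive co-occurrence is
  the nomination criterion.

Candidates are ranked by the number of distinct linked genomes (paralogs in
one genome count once, mirroring presence/absence logic), ties by
chi-square statistic, then family id.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `evalue_max` | 0.1 | E-value | permissive homolog capture; the boundary is inclusive (a hit at exactly 0.1 is kept) |
| `radius` | 10 | genes | ten genes upstream and downstream of the Se region |
| `max_gap` | 3 | genes | lets operon-scale clusters absorb small insertions without merging distant loci |
| `min_recurrence` | 3 | genomes | one genome is an anecdote, two could be one transfer event; three distinct genomes is the smallest defensible recurrence |
| `min_phyla` | 2 | phyla | linked genomes must span at least two phyla (when lineages exist), so a single clade's operon cannot drive a nomination |
| `min_freq` | 0.9 | fraction | consensus frequency for calling a conserved column |
| `yates` | TRUE | — | continuity correction for 2x2 tables; can be disabled |

Best-hit ties are resolved by minimal E-value, then maximal bitscore, then
lexicographic subject id, which makes BBH output independent of row order
and genome iteration order. A reciprocal tie cannot survive the
lexicographic fallback.

## The synthetic compendium

`simulate_se_compendium()` generates the study conditions under which the
pipeline is validated. Its defaults were fixed once, before any recovery
experiment, and are not tuned:

* **Species tree.** Yule process with unit per-lineage split rate: with
  $k$ lineages all branches grow by an $\mathrm{Exp}(k)$ hold time, a
  uniform lineage splits, and a final $\mathrm{Exp}(n)$ epoch gives the
  last-born tips positive pendant edges. The expected root-to-tip depth is
  the harmonic sum $\sum_{k=2}^{n} 1/k$, which the tests use as a
  Monte-Carlo oracle. Default 50 taxa.
* **Trait evolution.** Each marker family follows an independent two-state
  Markov chain with closed-form branch transition probabilities
  $P(0\to1 \mid t) = \frac{\alpha}{\alpha+\beta}(1 - e^{-(\alpha+\beta)t})$.
  Root states are *present* (an ancient trait subsequently lost), total
  rate 1, and stationary frequencies of 0.3–0.6 per family chosen so that
  trait prevalences land in the tens of percent — the mosaic regime where
  presence/absence statistics are informative. Trait correlation arises
  only through the shared tree and the shared SelD requirement; there is no
  explicit cross-family rate coupling.
* **Layout.** 250 genes on one replicon per genome (windows never span
  replicons, so one replicon loses nothing). SelD-positive genomes receive
  their present markers as one contiguous island at a uniform position;
  each of the four planted candidates (YedE, YedF, LysR_Se, DUF3343
  analogs) lands inside the island's ±10-gene window with probability
  `p_link` = 0.9, otherwise uniformly anywhere — so with `p_link` = 0 the
  in-window rate collapses to the uniform null (window span divided by
  genome size), which the tests check. Candidates also appear at a 5%
  background rate in island-free genomes, 200 background families at 50%
  presence fill the rest, and a 3-paralog LysR-like superfamily places its
  Se subfamily copy island-linked.
* **Habitat and lineage.** Aquatic probability 0.6 for SelD-positive
  genomes versus 0.3 otherwise — a planted association of the magnitude the
  habitat summary is meant to detect. Phylum labels are carved from the
  tree by average-linkage clustering of cophenetic distances (5 phyla, 10
  subdivisions), so lineage structure is consistent with the tree.
* **Homology noise.** True ortholog hits draw E-values log-uniformly from
  $[10^{-50}, 10^{-5}]$; spurious hits arrive at 2% per query-genome with
  E-values log-uniform across $[10^{-3}, 10]$, straddling the 0.1 cutoff so
  that filtering is actually exercised.

What the generator does **not** emulate: real sequence evolution (no
alignments for the whole compendium; MSAs come from a separate uniform
generator with planted conserved columns), horizontal transfer beyond what
gain/loss implies, multi-replicon genomes, operon strandedness, and
paper-scale genome counts. Passing recovery tests therefore demonstrate
that the algorithms are correct and well calibrated under a faithful
statistical cartoon of the data — not that any particular biological
dataset will yield the same candidates.

## Numerical choices

* Chi-square p-values are the exact df = 1 survival function
  (`pchisq(..., lower.tail = FALSE)`), never floored at 2.2e-16; the tests
  cross-check them against an independent complementary-error-function
  route to 1e-10. A table with a zero margin is reported as statistic 0,
  p = 1, flagged degenerate, rather than NaN.
* Clade enrichment uses the Fisher exact test because clades are small;
  chi-square remains available for profile-scale tables. The two-sided
  Fisher sums point probabilities within a $1 + 10^{-7}$ relative tolerance
  of the observed one (the standard convention).
* Neighbor joining breaks Q-criterion ties by the smallest index pair and
  clamps negative branch estimates to zero, recording the clamped deficit
  as an attribute. Distance matrices must be symmetric within 1e-9. A
  2-taxon input yields a 2-tip tree whose pendant edges sum to the input
  distance (a literal single edge is not representable in the `phylo`
  container).
* Poisson distances cap saturated pairs (p-distance = 1) at a configurable
  maximum (default 10) and flag them; a pair with zero comparable columns
  is an error naming the pair. PROTDIST-style model matrices (Dayhoff/JTT)
  are out of scope — externally computed PHYLIP square matrices are
  accepted as input instead, and at these scales the distance model rarely
  changes an NJ topology.
* Conservation scans skip columns with more than 50% gaps; consensus ties
  resolve to the alphabetically first residue.

## Design decisions that were genuinely open

* **Island-seeded windows.** Windows are taken around island spans and
  unioned, not around every known-Se gene in isolation; isolated marker
  genes outside islands still found islands of size one, but the
  neighborhood statistic is anchored on clustered regions, which is where
  the discovery signal lives. Automating island selection replaces the
  hand-picked representative regions a human analyst would choose; results
  may differ at the margins for genomes with fragmented clusters.
* **Orphan-SelD derivation.** The exclusion list is computed from the trait
  definitions rather than hard-coded, at the cost of an edge case: a
  user-defined trait equal to the signature alone would blur the orphan
  notion (the defaults cannot).
* **Genomic-location confirmation of orthologs** is realized as a
  reported check (does the assigned gene sit in an island?) that never
  overrides BBH, since no principled override rule exists.
* **E-value cutoff in both directions.** The 0.1 cutoff is applied to both
  the forward and reverse searches before BBH; a flag
  (`filter_hits` on each table separately) relaxes this if asymmetric
  filtering is wanted.
* **Trait classification uses machinery only** — no requirement that a
  Sec-decoding genome also encode a selenoprotein; detecting selenoprotein
  genes is a different (gene-finding) problem.
* **Yates correction on by default** for user-facing 2x2 tests, matching
  the convention of standard statistical environments; the type-I
  calibration in the test suite asserts the uncorrected Pearson statistic,
  whose rejection rate is the one with a nominal 5% target, and reports
  rather than asserts the conservative corrected variant.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale by choice:
50-genome default compendia (250 genes each), 100 random score matrices up
to 10x10 for BBH, 500 random tables for the chi-square oracle, 50 random
additive matrices of 5–10 taxa for NJ, 1,000 replicates for the type-I
calibration on a 200-leaf star tree, and trees of at most 14 leaves for
exhaustive clade enumeration. Every stochastic step flows from an explicit
seed; the simulate → classify → nominate chain is bit-identical across
reruns for a fixed seed, and the report writer keeps timestamps out of all
files except the run log.

## Known limitations

* Circular replicons are treated as linear: no wrap-around windows or
  islands. A flag is reserved for a future version.
* Habitat vocabulary is fixed to aquatic / nonaquatic / unknown; unknown
  genomes are excluded from habitat denominators.
* The clade-enrichment scan formalizes what is usually a visual call on a
  published tree; the minimal-p clade under a one-sided Fisher test is this
  package's definition, and reports label it as such.
* STRING-style functional-association evidence, transmembrane prediction,
  alignment construction, and likelihood/Bayesian tree inference are out of
  scope; the package consumes their outputs (hit tables, MSAs, trees) as
  inputs.
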
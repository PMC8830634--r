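---
title: "Comparative gene-family evolution with famevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative gene-family evolution with famevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famevol)
```

# The analysis

famevol implements a comparative analysis of multigene families — built
around the five insect detoxification families (cytochrome P450
monooxygenases, glutathione S-transferases, carboxyl/cholinesterases,
UDP-glycosyltransferases and ABC transporters) across a clade such as the
aphid subfamily Aphidinae — in four stages:

1. **Family annotation.** Curated seed proteins of a family are searched
   against each species' proteome by maximum-scoring local alignment
   (Smith–Waterman, BLOSUM62, affine gaps −11/−1), keeping hits with
   Karlin–Altschul E-value ≤ 10⁻⁵. Hits are then *exchanged with the
   seeds* and searched back against the seed species' proteome, so family
   members detectable only through an intermediate homolog are recovered
   (one reciprocal round; `annotate_families`). Candidates lacking the
   family's characteristic domain (an InterProScan-style annotation table
   supplied as input) are discarded. The result is a per-species gene
   count table per family.

2. **Gene trees.** Each family is aligned progressively (UPGMA guide tree
   on global-alignment identity distances; profile–profile alignment with
   mean-of-pairs scores), gap-rich columns are removed, and a
   neighbor-joining tree is built from Poisson-corrected distances
   $d = -\ln(1 - p)$. Supports come from resampling alignment columns
   with replacement and counting the fraction of replicate trees
   containing each bipartition (default 1000 replicates). Genes are
   assigned to subfamilies by clading with labelled reference genes: a
   leaf takes the label of the smallest enclosing clade whose labelled
   members are unanimous, else it stays "unassigned".

3. **Gain–loss reconciliation.** Internal edges with bootstrap support
   below 70 are contracted; the condensed tree is rooted wherever the
   duplication–loss (DL) parsimony cost is minimal, with polytomies
   resolved optimally; and the binary tree is reconciled with the species
   tree under the LCA mapping. Each gene node maps to the most recent
   common ancestor of its descendants' species; a node is a duplication
   iff it maps to the same species node as one of its children; losses
   are counted from the depth differences along mapped paths and charged
   to the species branches they occur on. Ancestral copy numbers follow
   by propagating `copies(child) = copies(parent) + gains − losses` from
   the root tipward, and every leaf is checked against the observed count.

4. **Relative evolutionary rates.** For each family and subfamily, all
   within-species gene pairs yield $n(n-1)/2$ percent-identity values per
   species, and all cross-species pairs (the among-species sample, with
   within-species rows removed) yield the complementary sample. Higher
   identity ⇔ slower evolution, so groups are ranked fastest-first by
   ascending mean identity, and the within- and among-species rankings
   are compared by their Kendall inversion count.

# Conventions and parameters

* **Percent identity** is `100 × identities / alignment columns`, with gap
  columns in the denominator (the BLAST `pident` convention over the
  aligned region). Pairs whose best local alignment is not significant
  (E-value above the search threshold, default 10⁻⁵ against the group's
  total residue count) are excluded from identity samples — exactly as a
  database search reports no row for them — rather than scored 0; for
  very divergent groups this biases means upward, which the report
  surfaces through the sample counts. A group with *no* significant pair
  at all is ranked fastest of all by `rank_by_identity`: no detectable
  similarity places its identity below every measurable group's
  detection floor.
* **E-values** use the ungapped BLOSUM62 Karlin–Altschul constants
  (λ = 0.267, K = 0.041) with the database size equal to the target
  proteome's residue count; exact BLAST composition-based statistics are
  deliberately not reproduced. 'X' residues score 0 against everything.
* **Pairs are unordered**: one value per gene pair (the best local
  alignment), self-hits excluded.
* **Support threshold**: an edge is kept iff support ≥ 70 (strictness at
  exactly 70: kept). The threshold, E-value cutoff and 1000 bootstrap
  replicates are the analysis defaults; every one is a config parameter.
* **Unit event weights** (duplication = loss = 1). The reconciliation
  cost includes stem losses from the species root down to the image of
  the gene root — a family observed in only one subtree pays one loss at
  the stem of each bypassed subtree — but no further losses inside an
  empty subtree.
* **Quartiles** use linear interpolation (R type 7); the spread statistic
  is the population standard deviation.
* **Minimum alignment length** for a search hit is 30 columns, guarding
  against spurious micro-alignments.

# Design choices where the method was open

* **NJ instead of maximum likelihood.** Tree inference is distance-based
  (NJ on Poisson-corrected distances). This is deterministic, desk-scale,
  and exactly correct on additive distances (tested); it is *not* an ML
  estimate, and externally computed trees can be supplied as newick
  whenever ML fidelity matters. Rate heterogeneity and model selection
  are out of scope.
* **Exact polytomy resolution.** Resolving a polytomy at minimum DL cost
  is done by a dynamic programme over the species tree: with the child
  subtrees' mappings fixed, `g_s(j)` is the minimal cost inside the
  species subtree at `s` given `j` gene lineages present at `s`. Because
  the LCA image of a polytomy's root is invariant under its resolution,
  polytomies can be resolved independently and the programme is optimal
  for any polytomy degree — verified against exhaustive enumeration of
  all binary refinements. (An enumerate-small/greedy-large split was
  considered and rejected: the DP is both exact and faster.)
* **Rooting** of gene trees is unspecified in the underlying method;
  famevol tries every edge and keeps the minimum-cost rooting, breaking
  ties by the lexicographically smallest root-bipartition signature so
  results are reproducible.
* **Reciprocal expansion** is exactly one round (two search passes), with
  the domain filter applied after the union of both rounds. Candidates a
  second pass would add beyond round two are not chased.
* **Subfamily assignment** for clades containing no reference gene is
  "unassigned" (the unanimity rule); assignment is evaluated on
  bipartition sides so it cannot depend on the arbitrary rooting of the
  NJ tree.

# The synthetic-data generator

`simulate_study()` produces a complete, fully labelled study set with no
external downloads. Its statistical structure mirrors what the analysis
assumes about real proteomes:

* **Species tree**: nine aphid-like taxa in two tribes
  (Macrosiphini / Aphidini), ultrametric with integer branch lengths and
  height 4 time units, the Acyrthosiphon genus pair with *S. avenae* as
  sister, and the Aphis genus pair — `default_species_tree()`.
* **Gene families** evolve by a linear birth–death process along the
  species tree: per lineage, duplications at rate λ and losses at rate μ
  with exponential waiting times; surviving lineages become extant genes.
  Defaults: λ = 0.2, μ = 0.05 per lineage per time unit, two root
  lineages per family (the planted subfamilies) joined by 2-unit stems
  above the species root (ancient duplications). These values give on the
  order of 30 genes per family across the nine species — large enough for
  every downstream statistic, small enough that the whole pipeline runs
  in seconds — with realistic lineage-specific expansions and losses.
* **Sequences** evolve site-independently under the equal-rates 20-state
  chain (or JTT) from a uniform-composition root; the expected divergence
  after rate×time $d$ is $\tfrac{19}{20}(1 - e^{-\tfrac{20}{19} d})$,
  which the tests verify at L = 2000. Default family rates 0.15 / 0.08 /
  0.03 substitutions·site⁻¹·time⁻¹ (a fast, an intermediate and a slow
  family) put cross-species identities in the 30–80% band typical of the
  real detoxification families, so the seeded search retains every true
  member at E ≤ 10⁻⁵.
* **Decoys**: five random-composition sequences per species with no
  domain annotation exercise the domain filter.
* **Seed sets** are the seed species' members of every subfamily; when
  drift removes a subfamily from the seed species entirely, the
  best-populated species contributes that subfamily's seeds (curated seed
  sets in practice cover all subfamilies, and the underlying study itself
  used two seed species for the ABC family).
* **Ground truth** records every event on its species branch, so
  `extant(leaf) = root_copies + births(path) − losses(path)` holds
  exactly and is asserted per leaf.

What the generator does *not* emulate: indels (alignment difficulty comes
only from substitution saturation), codon structure, rate variation
across sites, domain-architecture mosaicism, and annotation errors in
real proteomes. Green tests therefore demonstrate the correctness of the
algorithms under the stated model, not the field behaviour of the
pipeline on real, noisy proteomes.

# Numerical choices and degenerate inputs

* Poisson distances are capped at d = 10 (also used when two rows share
  no columns). Negative NJ branch lengths are clamped to 0. Distance
  labels are sorted before joining so NJ is order-invariant.
* The progressive aligner's profile gap score is −8 per residue–gap pair,
  gap–gap 0; DP ties break diagonal > up > left.
* Bootstrap resampling operates on canonically ordered rows, making
  supports independent of input row order given the seed.
* Empty proteomes, empty hit lists, single-member groups and
  one-species groups all return empty results with a warning or message,
  never an error; an all-extinct simulated family is flagged and
  resimulated by `simulate_study` (the attempt count is kept in the
  truth).
* Serialised outputs are fixed-precision (identities 3 decimals,
  E-values 2 significant digits), so repeated runs diff byte-for-byte.

# Problem sizes used by the shipped tests

The test suite regenerates everything it needs: the exhaustive
reconciliation check enumerates all gene trees with ≤ 6 leaves over all
three 3-species trees (≈ 172 000 cases), polytomy optimality uses 500
random multifurcating trees (≤ 8 leaves), loss-free recovery 200
simulated families, rate-order recovery 50 replicate studies at rates
0.1 / 0.4 / 1.0 (root_copies = 1, λ = 0.3, μ = 0.05, families
resimulated until they hold at least 10 genes in at least 2 species),
NJ recovery 100
additive matrices (≤ 10 taxa), and the end-to-end determinism check runs
the full pipeline twice at 100 bootstrap replicates. The acceptance
script reports the same quantities at reduced replication suited to its
runtime budget.

# Worked example

```{r example, eval = FALSE}
library(famevol)

fix <- file.path(tempdir(), "study")
make_fixture(default_sim_config(seed = 1), fix)

out <- file.path(tempdir(), "results")
run_all(run_config(fix, out, bootstrap_reps = 100, seed = 1))

read.csv(file.path(out, "counts.csv"))                 # per-species counts
read.csv(file.path(out, "reconciliation_summary.csv")) # gains / losses
read.csv(file.path(out, "rank_report.csv"))            # rate rankings
```

# Known limitations

* The search engine is exact Smith–Waterman, not a seeded heuristic; on
  proteome pairs far larger than the simulated studies it will be slower
  than BLAST while returning the alignments BLAST approximates.
* DL parsimony ignores transfer and gene conversion, and unit weights are
  an analysis convention, not an inference.
* Identity-based rate ranking compresses near saturation; for deeply
  diverged groups the excluded insignificant pairs and the
  local-alignment floor both bias identity upward, so ranks — not
  magnitudes — are the meaningful output.
* At rates fast enough that typical pairs sit beyond the significance
  horizon, the *within-species* sample retains only the most recent
  duplicates, truncated at a divergence horizon that does not depend on
  the rate; within-scope means of two sufficiently fast groups are then
  statistically tied, and only the among-species ranking carries signal.
  The within/among rank agreement the method reports is therefore
  meaningful in the detectable-divergence regime (where real
  detoxification families live), not under saturation.
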
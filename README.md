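# famevol

Comparative evolution of multigene families across a clade of species —
built for analyses like the five insect detoxification families
(cytochrome P450s, glutathione S-transferases, carboxyl/cholinesterases,
UDP-glycosyltransferases, ABC transporters) across nine aphid species,
and fully testable without any external downloads.

## What it does

Given per-species proteomes (FASTA), curated seed proteins per family,
a domain-annotation table and a species tree, famevol runs four stages:

1. **Family annotation** — seeded Smith–Waterman search (BLOSUM62,
   affine gaps −11/−1, Karlin–Altschul E ≤ 10⁻⁵), one reciprocal
   seed-exchange round, and filtering by the family's characteristic
   domain; output is a per-species gene count table.
2. **Gene trees** — progressive multiple alignment (UPGMA guide tree,
   profile–profile merging), gap-column trimming, neighbor joining on
   Poisson-corrected distances *d* = −ln(1 − *p*), and column-resampling
   bootstrap supports; subfamilies are assigned by clading with labelled
   reference genes.
3. **Gain–loss reconciliation** — branches with bootstrap support below
   70 are collapsed; the condensed tree is rooted at minimum
   duplication–loss cost with polytomies resolved exactly (a dynamic
   programme over the species tree); the LCA reconciliation yields
   per-branch gains and losses and ancestral copy numbers
   (copies(child) = copies(parent) + gains − losses, verified at every
   leaf).
4. **Rate comparison** — for every family and subfamily, within-species
   gene pairs give n(n−1)/2 percent-identity values per species and
   cross-species pairs give the among-species sample; groups are ranked
   fastest-first by ascending mean identity (higher identity ⇔ slower
   evolution) and the within- and among-species rankings are compared by
   their inversion count.

A birth–death simulator (`simulate_study()`, `make_fixture()`) generates
complete labelled study sets — species tree, families with planted
duplications/losses and subfamilies, sequences, domain tables, decoys —
so every stage is tested against known ground truth.

## Worked example

```r
library(famevol)

fix <- file.path(tempdir(), "study")
make_fixture(default_sim_config(seed = 1), fix)   # simulate 9 proteomes

out <- file.path(tempdir(), "results")
run_all(run_config(fix, out, bootstrap_reps = 100, seed = 1))

read.csv(file.path(out, "counts.csv"))
#>      species CCE GST P450
#> 1    A_pisum   3   4    3
#> 2   A_kondoi   2   3    2
#> 3   S_avenae   2   3    2
#> 4 M_persicae   5   4    4
#> ...
read.csv(file.path(out, "reconciliation_summary.csv"))
#>   family duplications losses total_cost
#> 1    CCE           12      2         14
#> 2    GST            6      1          7
#> 3   P450           10      1         11
read.csv(file.path(out, "rank_report.csv"))
#>     kind        within_order         among_order n_inversions
#> 1 family  P450 > CCE > GST    P450 > CCE > GST              0
```

The count table lists recovered family members per species (here they
match the simulator's truth exactly); the reconciliation summary gives
the inferred duplication and loss events per family after support
collapse and minimum-cost rooting; the rank report orders families from
fastest- to slowest-evolving by mean pairwise identity — P450 (planted
rate 0.15 subs/site/time) ahead of CCE (0.08) ahead of GST (0.03), with
the within- and among-species rankings in full agreement.

A thin command-line wrapper with the same stages is installed at
`inst/scripts/famevol` (`famevol simulate|annotate|tree|reconcile|rates|all`).

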
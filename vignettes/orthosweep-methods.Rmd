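---
title: "Filtering ortholog alignments and diagnosing gene-tree discordance with orthosweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering ortholog alignments and diagnosing gene-tree discordance with orthosweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Phylogenomic studies of closely related species — cryptic species complexes
in particular — assemble thousands of per-gene ortholog clusters from mixed
sources (transcriptomes, genome assemblies, whole-genome resequencing).
Before any tree is inferred, those clusters must be cleaned: mis-assigned
paralogs, mis-assembled or frameshifted sequences, truncated models and
N-masked low-coverage stretches all masquerade as orthologous coding
sequence, and each of them distorts gene trees in its own way. After
cleaning, the question inverts: given thousands of gene trees that
*disagree* with each other (incomplete lineage sorting guarantees they
will), how much support does each species-tree branch really have, and how
few loci suffice for a reliable diagnostic panel?

orthosweep implements both halves at desk scale: a three-step filter over
codon alignments, per-branch concordance statistics, a quartet-agreement
species-tree estimator, a locus-subsampling experiment, a locus-independence
summary, and a coalescent simulator that makes the whole chain testable with
no external data.

## The three-step filter

Each ortholog cluster passes through three filters, each followed by a fresh
round of codon-aware alignment and trimming:

1. **Reading frame and length variation.** Sequences are stripped of gaps
   and terminal `N` runs, then removed if their length is not a multiple of
   three or if they contain an internal stop codon. The surviving lengths
   define a mean; any sequence outside
   `mean * (1 ± len_var_pct/100)` is removed, in a *single pass* against
   that original mean (default `len_var_pct = 30`).
2. **Mean pairwise distance.** On the codon alignment, the uncorrected
   p-distance between two rows is `100 * mismatches / compared sites`,
   where compared sites are columns with an unambiguous base (`A/C/G/T`)
   in both rows. A sequence is removed when the mean of its off-diagonal
   distances is strictly greater than `max_mean_dist` (default 25%), again
   in one simultaneous pass. `distance_threshold_stats()` reports the mean,
   SD and median of per-cluster maximum distances so the threshold can be
   anchored on the data: when the SD rivals the mean, the median is the
   more stable reference point.
3. **Missingness.** On the re-aligned survivors, a row is removed when its
   fraction of `N` plus `-` cells is strictly greater than
   `max_missing_frac` (default 0.25).

Finally the occupancy filter keeps clusters with at least `min_samples`
surviving samples and reports the matching gene-occupancy percentage
(`round(100 * min_samples / total_samples)`).

Three semantics are worth stating explicitly because they are easy to get
wrong when re-deriving the pipeline:

* **Every comparison is strict** (`>`), so a row at exactly the threshold
  survives.
* **Filters are single-pass**: statistics are computed once, before any
  removal, and are not iterated to convergence after removals.
* **Undefined distances** (pairs with zero compared sites) enter the
  per-row mean at 100, the maximum possible value: two sequences that share
  no unambiguous site cannot be verified as orthologous, and the design
  treats that as evidence against them rather than silence.

The per-record audit trail (`FilterReport`) partitions the input exactly:
every record appears once, either with the step and reason of its removal
(`prep`, `length_set`, `distance`, `missingness`, `occupancy`) or as
retained.

## Codon-aware alignment

Alignment operates at the protein level and is projected back to codons:

* `check_and_translate()` validates the open reading frame (standard
  genetic code; one terminal stop is permitted and trimmed; codons
  containing `N` translate to `X`).
* `align_proteins()` is a deterministic progressive aligner: a UPGMA guide
  tree over k-mer (k = 3) distances, then profile–profile global alignment
  under BLOSUM62 with affine gaps (open 10, extend 1). Sequences are
  ordered lexicographically by sample id before guide-tree construction so
  ties resolve identically on every run. An `aligner_cmd` hook substitutes
  any external FASTA-to-aligned-FASTA tool when bit-compatibility with a
  published aligner is needed.
* `trim_columns()` retains a column iff its gap fraction is at most
  `max_gap_frac` (default 0.2) *and* the modal-residue fraction among
  non-gap cells is at least `min_conservation` (default 0.25). This
  explicit two-threshold rule approximates the intent of strict
  "poorly aligned region" trimmers with a rule that can be recomputed
  per column by inspection.
* `backtranslate()` maps residue `j` of a row to codon `j` of its CDS,
  counting non-gap cells only; gaps become `---`. The composition
  invariant — ungapping any codon row yields whole codons of the original
  CDS, in order — is tested exactly.

Two scoring choices matter for contaminated data. `X` (a masked or
ambiguous codon) is scored **zero against everything**, not with the
BLOSUM62 `X` column: BLOSUM's `X` penalties model an unknown *residue*,
whereas here `X` means *missing data*, which should neither attract nor
repel any alignment. For the same reason k-mers containing `X` are dropped
from guide-tree distances. Without this, heavily masked sequences cluster
with each other and with diverged contaminants and then misalign, sending
them to the wrong filter step.

## Concordance statistics

All tree statistics are bipartition-based:

* `rf_distance()` counts the symmetric difference of non-trivial
  bipartitions (unrooted mode) or non-root clades (rooted mode), optionally
  after pruning both trees to their shared leaves. Rooted mode is the
  default in the subsampling experiment because the reference comparison
  there is between outgroup-rooted trees.
* `gene_concordance_factor()`: for a species-tree branch `A|B`, a gene tree
  is *decisive* when at least two leaves of each side survive restriction
  to its leaf set, and *concordant* when the restricted bipartition occurs
  among its splits. A polytomy is decisive but not concordant. The factor
  is `100 * concordant / decisive`.
* `quartet_support()`: around each internal branch the four adjacent
  subtree clusters define quartets (one leaf per cluster); over gene trees
  containing the four sampled leaves, the three possible topologies are
  tallied (`q1` concordant, `q2`/`q3` alternatives; unresolved quartets are
  skipped). Enumeration is exhaustive up to `max_quartets_per_branch`
  (default 1000) and seeded uniform sampling beyond.

Quartet topologies are read off unit-branch-length path distances through
the four-point condition, which is exact on trees and marks star quartets
as unresolved.

## Quartet-agreement species-tree estimation

The estimator maximises the number of gene-tree quartets compatible with a
candidate topology, the same quantity that underlies quartet-based
coalescent summary methods. Two search modes share one scorer:

* `exhaustive_search()` enumerates all unrooted topologies by stepwise leaf
  addition (practical to 8 taxa, 10,395 topologies) and is the oracle the
  heuristic is tested against; co-optima are reported and ties broken by
  the lexicographically smallest canonical Newick.
* `greedy_search()` inserts taxa in seeded random order, each at the
  score-maximising edge, then hill-climbs with nearest-neighbour
  interchanges, accepting only strict improvements, so the NNI phase can
  never decrease the score and termination is guaranteed.

Branch lengths are not estimated; the output is a topology whose support is
then quantified with the concordance statistics above. Missing taxa
contribute only the quartets they are part of.

## The subsampling experiment

`run_experiment()` draws, for each subset size and replicate, a multiset of
gene trees (*with replacement*), accepts a draw only if every specimen
occurs in at least `min_coverage` **distinct** drawn trees (a duplicated
copy adds no information, so it cannot satisfy coverage twice), estimates a
species tree, roots it on the named outgroup, prunes the outgroup, and
records the rooted RF distance to the reference plus the recovery of each
reference clade. Draws violating coverage are redrawn up to `max_attempts`
(default 1000); exhaustion is an error, never a silent relaxation, and
infeasible configurations fail upfront naming the offending specimen. The
whole table is reproducible from the configuration seed: each (size,
replicate) cell uses an independently derived substream.

The per-size summary (clade recovery proportions; RF median and quartiles)
is exactly the export a saturation figure is drawn from: recovery rises
with subset size and the RF distribution contracts, flattening at the size
where the panel carries as much resolution as the full set — with clades
subtended by very short internal branches plateauing low, visibly
recalcitrant to more loci.

## Locus independence

With point coordinates (the first base of each locus), a locus is
*isolated* when its nearest same-chromosome neighbour is strictly farther
than `independence_dist` (default 100 kb; a locus alone on its chromosome
counts as isolated), while single-linkage clusters join loci at distances
up to and *including* the threshold. The number of clusters is the number
of potentially independent loci; isolated loci are always singleton
clusters, so `n_independent >= n_isolated` by construction. Bin counts use
half-open 0-based bins (`floor((pos - 1) / bin_size)`, default 500 kb), so
position 500,000 falls in the first bin and 500,001 in the second, and
totals are conserved for any bin size.

## The synthetic-data generator

`simulate_dataset()` produces the full chain of inputs with ground truth:

* a pure-birth species tree (default root age 3 coalescent units — deep
  enough for a few percent of sequence divergence at the default rate,
  typical of congeneric ortholog sets);
* multispecies-coalescent gene trees: within each species-tree branch,
  lineages coalesce with exponential waiting times at rate `choose(j, 2)`
  per coalescent unit. On a three-taxon tree with internal branch `t` the
  probability that a gene tree matches the species tree is
  `1 - (2/3) exp(-t)`, and the simulator is tested against this closed
  form at `t` in {0, 0.5, 1, 2};
* codon sequences under an equal-rates model with stop-codon rejection
  (default 0.01 substitutions per site per coalescent unit), so every
  clean sequence passes the reading-frame check by construction;
* injected artifacts with a manifest: `paralog` adds 1.5 expected
  substitutions per site (about 65% p-distance — far beyond the default
  distance threshold, as a duplicate diverged well before the ingroup
  radiation would be), `frameshift` deletes one base, `truncate` removes
  the trailing half of the codons, `mask` replaces one contiguous interior
  block of 60% of sites with `N`.

Masking is contiguous and interior by design: coverage gaps in real
assemblies are contiguous, and a block that avoids the terminal codons
survives end-trimming with its reading frame intact, which is what lets the
missingness filter (not the frame check) be the step that catches it.
Scattered per-site masking at comparable rates leaves almost no intact
codon (`0.4^3` of codons survive at 60% masking) and produces sequences no
aligner could place — a failure mode of the data, not of the filter.

Randomness flows from one seed through counter-based substreams (per gene,
per cluster, keyed by cluster id for artifact injection), so per-cluster
outputs do not depend on iteration order or on which other clusters are
simulated.

What the generator does **not** emulate: introgression (discordance is ILS
only), indels (clean sequences stay equal-length, so the length filter is
exercised only by injected truncations), rate variation across sites or
lineages, and codon-usage or selection effects. Passing tests therefore
demonstrate the machinery's correctness and its behaviour under the stated
contamination model, not robustness to every artifact of real assemblies.

## Problem sizes and numerical choices

The test suite and the acceptance script run, as the package's own choice
of desk-scale study conditions: 12 species × 6 clusters × 100 codons for
the artifact-recovery runs (20 and 8 seeds respectively); 3000 gene trees
per point for the coalescent closed form; 8 species × 300 gene trees with
internal branches of at least one coalescent unit for species-tree
recovery; and a 123-gene panel over 11 species (one outgroup) with subset
sizes 10–110 for the subsampling experiment.

Other numerical conventions: occupancy percentages are rounded to the
nearest integer to match conventional labels; mean alignment length is
reported to two decimals; sample standard deviation is used in the distance
statistics, with a single-cluster SD reported as 0 with a warning; RF
comparisons in the experiment prune the outgroup after rooting (rooting is
the outgroup's only role); all searches break ties deterministically
(first-found maximum over a canonically ordered candidate list).

## Worked example

```{r example}
library(orthosweep)

sim <- simulate_dataset(n_species = 12, n_genes = 6, n_codons = 100, seed = 1)
res <- run_pipeline(sim$clusters, filter_params(min_samples = 2))
res$summary
table(merge(sim$manifest, res$report,
            by = c("cluster_id", "sample_id"))[, c("artifact", "step")])

sp <- greedy_search(sim$gene_trees, seed = 1)
branch_concordance(sp$tree, sim$gene_trees, seed = 1)
```

## Limitations

The built-in aligner and trimmer are reproducible stand-ins with explicit
rules, not re-implementations of any published tool's heuristics; command
hooks exist for bit-exact parity where that matters. The species-tree
estimator optimises quartet agreement greedily and is meant for panels of
tens of taxa, not hundreds. The gene concordance factor requires exact
bipartition matches, so near-misses count as discordant. All statistics
assume leaf labels are consistent across trees and clusters; no label
normalisation is attempted.
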
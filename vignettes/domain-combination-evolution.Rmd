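---
title: "Reconstructing the parallel evolution of protein domain combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the parallel evolution of protein domain combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combevol)
```

## The question and the model

Most eukaryotic proteins are multidomain, and new domain arrangements arise
readily from genome rearrangements. `combevol` asks how often the *same*
directed binary domain combination (an ordered pair A~B, with A N-terminal
to B) has been created independently in different lineages, rather than
inherited from a common ancestor.

The analysis unit is the directed binary combination, not the full
architecture: a protein with domains A, B, C (N→C) contributes A~B, A~C and
B~C. Order matters (A~B ≠ B~A), and pairs of identical domains are never
counted — an A-B-B protein yields only A~B, because repeats of the same
domain can arise by local duplication and cannot be attributed to fusion
without per-family phylogenies. An architecture such as A-B-A genuinely
contains both A~B and B~A and contributes both. Two alternative models are
available for sensitivity analysis: undirected pairs (A~B ≡ B~A,
canonically ordered), and adjacent-only pairs (A-B-C yields A~B and B~C but
not A~C).

Each genome's repertoire is the *set* of combinations across its proteins —
presence/absence throughout; copy number within a genome is deliberately
ignored, so parallel emergence between paralogs inside one genome is out of
scope.

## Ancestral reconstruction

Repertoires are mapped onto the tips of a rooted species tree and each
combination is treated as an independent binary character. Ancestral
presence/absence is reconstructed by unweighted parsimony: gains (fusion)
and losses (fission) cost equally, which encodes the assumption that the
two processes are, on average, comparably likely. Individual domains — whose
de novo invention is far rarer than recombination — are reconstructed under
Dollo parsimony instead: a single gain at the LCA of all carriers, plus the
minimal set of losses (one per maximal carrier-free subtree of the gain
clade).

The Fitch engine is implemented as a unit-cost dynamic program over node
states (the Sankoff recursion restricted to two states). This matters for
two reasons. First, it is exact on multifurcations, where the classical
two-child set rule is not; taxonomy-derived trees are full of polytomies
and we retain them as given rather than forcibly binarizing. Second, it
gives a clean separation between the *minimum* (the bottom-up cost table)
and the *chosen reconstruction* (a top-down pass), which is where ties must
be broken.

### Tie-breaking and the root

The minimum number of changes is unique; the placement of gains and losses
often is not. The package resolves ties deterministically:

* the root takes state 0 when both root states are equally parsimonious
  (`root_preference = "absent"`, the default): a combination absent from
  the analysis would trivially be absent ancestrally. The alternative
  (`"present"`) is exposed so users can bound the effect of this prior;
  it never changes the change count, only the gain/loss split.
* each ambiguous child adopts its parent's resolved state.

A combination reconstructed as present at the root counts as one
*appearance* but not as an edge change. Results therefore carry both
`total_changes` (edge changes; always equal to the global minimum) and
`total_events` (gains including a root appearance, plus losses). On a star
tree with *n* tips and *k* carriers these are min(k, n−k) and
min(k, 1+(n−k)) respectively.

### Origin counting

A combination's number of independent origins is its number of gain nodes
(root appearance included). Combinations with ≥2 origins evolved in
parallel. The headline statistics are the share of all distinct
combinations with ≥2 origins, and the same count as a share of *recurring*
(non-species-specific) combinations. Per genome, a combination counts as
"independently evolved elsewhere" when it has ≥2 gains of which at least
one lies off the genome's root path; a gain at an internal node is an
origin shared by all carrier descendants. For the evolutionary-distance
profile, every unordered pair of gain nodes of a combination contributes
one count to the pair's LCA (when one gain is ancestral to the other, the
LCA is the ancestral gain node itself — such pairs can arise via
gain/loss/re-gain along one lineage), and per-node counts are normalized by
the node's number of descendant genomes.

## Input processing

Hits arrive as HMMER3 `domtblout` tables (hmmscan orientation) or as the
package's generic TSV. Filtering supports Pfam's per-family bit-score
thresholds — gathering (GA), trusted (TC, stricter), noise (NC, looser) —
or a uniform independent-E-value cutoff; domain families associated with
viruses, transposons and bacteriophages can be excluded by an accession
list. Overlapping hits on a protein (sharing ≥1 residue under 1-based
inclusive envelope coordinates) are resolved by greedy acceptance in
ascending independent-E-value order, so only the most significant of a set
of overlapping matches survives. Ties are broken by descending bit score,
then accession, then start position — the data rarely exercise these, but
determinism requires a total order. Envelope (not alignment) coordinates
are used because they bound the hit's full extent.

The clan-level rerun replaces every domain token by its Pfam clan (domains
without a clan are kept) and repeats the whole analysis; pairs that
collapse onto the same clan become self-pairs and are excluded, exactly as
at the domain level. This tests whether apparent re-invention is an
artifact of highly divergent domains being scored as different families.

## The synthetic generator

Real multi-genome datasets are large and tied to external databases, so
the package ships a generator that emulates the process the parsimony
model assumes, with a complete truth log:

* a rooted binary tree from a Yule process (`generate_tree`);
* a fixed domain pool, all present everywhere (domain content is not
  simulated — only combination presence evolves);
* along each branch, Poisson-distributed fusion and fission events in
  random interleaved order: a fusion creates an ordered pair currently
  absent on the lineage (re-creation of a pair lost or gained elsewhere is
  what produces parallel evolution); a fission removes a present pair;
* tip repertoires materialized as two-domain proteins plus single-domain
  proteins for unused domains, emitted as a hit table with non-overlapping
  coordinates and scores passing the accompanying synthetic cutoff table
  in every mode, so the full ingest path is exercised.

Defaults (chosen once as a realistic desk-scale study and not revisited):
20 genomes, a 40-domain pool, 60 ancestral combinations, fusion rate =
fission rate = 0.5 expected events per branch — the equal-rates regime
unweighted parsimony assumes — with a fusion-biased preset (0.6/0.4)
mirroring the reported tendency of fusion to outpace fission; half the
domains carry clans; one protein per combination. The truth-log replay
invariant (re-applying all events reproduces every tip repertoire) is
asserted on every run.

What the generator does *not* emulate: sequence-level evolution (scores
and coordinates are synthetic constants), rate heterogeneity across
branches and lineages, within-genome duplication dynamics, architectures
longer than two domains, and annotation noise. Passing recovery tests
therefore shows the inference machinery is correct under its own model
assumptions — not that real annotations are free of the coverage and
gene-model artifacts the method is known to be sensitive to.

### What recovery tests can and cannot show

With fission disabled, every gain leaves a permanent disjoint presence
clade and parsimony recovers the true origin count of essentially every
combination; the one exception is the coincidence of two sister lineages
independently gaining the same pair, which parsimony must merge into a
single ancestral gain (at the test's settings — 200 ancestral
combinations, fusion rate 0.3, a ~1,500-pair pool — the chance of any such
coincidence in a replicate is of order 10⁻³). With fission active,
parsimony systematically *undercounts* true origins (a re-gained
combination can be cheaper to explain as never lost), which the tests
assert as a distributional property. The published estimate should be read
the same way: as a lower bound.

## Numerical and design choices

* Characters are processed independently; the bottom-up pass is vectorized
  across characters, so dataset-scale matrices are one sweep.
* The exhaustive enumeration oracle (`brute_force_min_changes`) refuses
  trees with more than 20 internal nodes; it exists to validate the engine
  on small trees, not for production use.
* Degenerate inputs are defined, not exceptional: an all-absent character
  yields zero events; a genome with no domains reports an undefined
  (`NA`) combinations/domains² ratio; empty hit tables flow through as
  empty results.
* Reports carry raw values alongside rounded ones (percentages to one
  decimal) since published figures mix roundings.
* The packaged eukaryote topology is a clade-level fixture (tips are major
  clades such as Deuterostomia, Neoptera, Micromonas, Dikarya) for worked
  examples and documentation; real analyses should supply their own
  species tree, in Newick or phyloXML.
* Problem sizes used in the shipped tests and the acceptance script — up
  to ~20 genomes, a few hundred characters, 500-case oracle sweeps, 10–20
  simulation replicates — were chosen so the whole suite completes in
  about a minute while still exercising every code path at meaningful
  scale.

## Worked example

```{r example}
tree <- eukaryote_tree()
pattern <- plant_pattern(tree, c("Deuterostomia", "Protostomia", "Micromonas"))
fitch_binary(tree, pattern, character = "KH~DEAD")
dollo_binary(tree, pattern, character = "KH~DEAD")
```

The combination present in bilaterian animals and in a green-alga lineage,
but nowhere in between, reconstructs as two independent gains; forcing a
single ancestral origin (the Dollo reconstruction) costs one gain plus
thirteen losses on this topology, which is why unweighted parsimony
prefers the parallel-evolution explanation.

```{r pipeline}
sim <- simulate_evolution(params = sim_params(
  n_tips = 12, gain_rate = 2, loss_rate = 2, seed = 5))
dir <- file.path(tempdir(), "sim")
write_simulation(sim, dir)
res <- run_pipeline(run_config(
  hits = file.path(dir, "hits.tsv"), tree = file.path(dir, "tree.nwk"),
  cutoffs = file.path(dir, "cutoffs.tsv"), clans = file.path(dir, "clans.tsv"),
  supergroups = file.path(dir, "supergroups.tsv"),
  out_dir = file.path(tempdir(), "out")))
res$pct
head(res$per_genome)
```

## Known limitations

* Parsimony reconstructions are lower bounds on event counts; no
  likelihood model, branch lengths or rate estimation is attempted.
* Within-genome (paralog-level) parallel evolution is invisible to
  presence/absence repertoires.
* The per-genome "independently evolved elsewhere" ratio depends on the
  declared tie-break for equally parsimonious reconstructions; both root
  preferences are exposed so users can bound this.
* Clade-specific and core sets are sensitive to taxon sampling: a
  "species-specific" combination is only specific with respect to the
  genomes analyzed.
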
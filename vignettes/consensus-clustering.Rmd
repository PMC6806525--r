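---
title: "Consensus clustering of RNA 3D decoys across homologs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus clustering of RNA 3D decoys across homologs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnacore)
```

## The model behind the pipeline

Homologous RNAs share a conserved structural core: the helices and
junctions that define the fold recur across the family, while peripheral
insertions vary. If one folds the target sequence *and* several homologs
independently, the correct global arrangement of the core should appear
repeatedly across the pooled decoy sets, whereas folding artifacts
scatter. The pipeline makes this operational in four steps: extract the
core from the alignment, compare all pooled decoys over that core,
cluster, and take the first target-sequence model from the clustering
output.

The assumptions worth stating explicitly:

* every selected homolog actually folds into the family core — a
  mis-assigned or truncated sequence degrades the consensus;
* decoy sets are ranked by energy, and the best-ranked fraction contains
  at least some near-native cores;
* the alignment is structurally correct at the core columns, since the
  cross-homolog residue correspondence comes entirely from it.

## Core extraction

A core column is one that is ungapped in **all** selected sequences. The
`min_ungapped_fraction` argument of `conserved_core()` relaxes this (a
column qualifies when at least that fraction of sequences is ungapped),
but the default of 1 is the behavior the rest of the pipeline assumes;
with a lower fraction, sequences gapped at a retained column simply
cannot be traced there and error out at `core_trace()`. No conservation
scoring is applied on top of the gap rule: being common to all selected
sequences is the operative definition of "conserved" here, and anything
stricter is left to the user's choice of alignment and sequences.

Redundancy reduction (`reduce_redundancy()`) is a greedy scan in record
order with a pairwise identity threshold (default 0.9). Identity is
matches over columns where at least one sequence is non-gap; gap–gap
columns are ignored and ambiguity codes always count as mismatches. The
greedy-in-order rule is deliberately simple: it is deterministic, so a
given alignment always reduces to the same kept set, which matters more
for reproducibility than squeezing out an optimal subset.

## Core RMSD and superposition

Cross-homolog comparison uses one atom per core residue, the ribose C3′.
Full-atom RMSD is impossible across different sequences (the atom sets
differ); one backbone atom per aligned residue is the coarsest
representation that still pins down the global helical arrangement.
Superposition is the covariance-SVD (Kabsch) construction with a
determinant sign correction so that only proper rotations are returned;
the reported RMSD is the exact minimum over rigid motions. Degenerate
inputs — fewer than three points, or collinear point sets (second
singular value below `1e-8` relative tolerance) — are rejected rather
than silently fitted, because a collinear core has no well-defined
rotation and any answer would be noise.

The all-vs-all matrix computes each pair once from pre-centered traces
(the pair cost is a 3×3 cross-covariance and its SVD) and mirrors it, so
symmetry and the zero diagonal hold exactly by construction.

## The clustering routine

Neighbors are pairs with core RMSD strictly below the cutoff; a model is
not its own neighbor. Strict `<` keeps the singleton logic clean: at a
cutoff below the minimum pairwise distance every model has zero
neighbors and forms its own cluster. Greedy extraction picks the
unassigned model with the most unassigned neighbors as medoid and
removes it with its neighbors; ties are broken by lower energy rank,
then lexicographic id. The tie-break is not in the original description,
which is silent on the point; some deterministic rule is required for
testing, and energy rank is the only meaningful prior ordering the
inputs carry.

The cutoff search starts at 0.5 Å and steps by 0.5 Å until the stopping
criterion holds. The integer thresholds are `ceiling(n/6)` (1-of-6 mode:
first cluster) and `ceiling(n/2)` (half mode: top three clusters
combined), which for 500 pooled structures give 84 ("over 80") and 250.
A `max_cutoff` guard (default 50 Å) turns a pathological non-terminating
search into an error that reports the trajectory of first-cluster sizes,
which is the diagnostic one actually wants when a matrix fails to
percolate.

## Selecting the final model

Two published rules are implemented. `cluster_scan` (default) walks the
clustering output in order — clusters by extraction, members by distance
to the medoid — and returns the first model belonging to the target
sequence; this is the procedural description of the method and is what
the cluster report file encodes. `max_neighbors` returns the target
model with the most neighbors at the terminating cutoff. The two rules
can genuinely disagree (a dense target model may sit in the second
cluster), so the report records which rule fired and lists the remaining
target models in scan order as runner-ups.

## Evaluation metrics

Heavy-atom RMSD is only computed between models of the same residue
count (prediction vs reference for the same sequence), with per-residue
atom-name intersection because decoys differ in atom completeness.
Interaction Network Fidelity is the geometric mean of precision and
recall over base-base interaction sets; it is reported as `NA` when a
denominator is zero, never coerced to 0, since a silent zero would be
indistinguishable from a genuinely wrong prediction. Interaction sets
can be supplied as dot-bracket strings (pseudoknot layers `()`, `[]`,
`{}` matched independently) or TSV lists; failing those, a minimal
geometric detector emits base pairs (C1′–C1′ distance in 8–12 Å and
closest Watson–Crick-edge atom contact under 3.5 Å) and stacks
(sequence-nonadjacent, base-centroid distance under 5.5 Å, plane-normal
angle under 30°). These thresholds are configurable defaults for
idealized and lightly noised geometry; the detector makes no claim to
reproduce a trained base-pair classifier, and both the base-pair-only
and stacking-only INF sub-scores are emitted so users can ignore the
cruder stacking calls.

## The synthetic generator

`make_fixture()` emulates exactly the input layout the pipeline
consumes: an aligned FASTA over a target plus homologs, a decoy
directory, and a mapping file. The core backbone is an idealized A-form
parameterization — rise 2.8 Å and twist 32.7° per step, C3′ at 9.4 Å
from the helix axis, the complementary strand offset 150° so paired
C1′–C1′ distances match A-form (~10.4 Å) — with an extended linker for
unpaired residues and per-homolog insertions placed on a separate
segment and gapped out in all other alignment rows (each insert block is
private to one sequence, so the conserved core is exactly the planted
core columns).

Planted cluster `k` applies a hinge motion to the second half of the
core: a rotation about the helix axis plus a translation of magnitude
`(k-1) * between_shift`. A hinge, not a whole-body motion, because core
RMSD is superposition-invariant: rigidly moving an entire model changes
nothing, and only an internal rearrangement separates clusters in the
metric. Each decoy then adds isotropic Gaussian jitter (sd
`within_sigma` per coordinate, default 1 Å) to every atom. With the
default 12 Å shift on half the core, between-cluster core RMSDs land
around 5–7 Å against within-cluster values near
`sigma * sqrt(6) ≈ 2.4` Å, a clean separation.

What the generator does **not** emulate: energy scores (ranks are
arbitrary within a homolog), compact non-helical tertiary contacts,
correlated (non-isotropic) decoy error, partially misfolded cores, or
alignment errors. Passing the planted-partition tests therefore shows
the machinery is correct — core mapping, metric, search, selection —
not that the consensus strategy succeeds on real folding ensembles,
where decoy error is structured and clusters are far less separable.

## Numerical and design choices

* Indices are 1-based everywhere (columns, residues, interactions), as
  is idiomatic in R; serialized artifacts round-trip through the
  package's own readers.
* Model rank within a homolog is lexicographic filename order (decoy
  exports are number-named), overridable by an explicit rank column in
  the mapping file.
* Residue identity is positional (chain order), not PDB numbering,
  because folding engines renumber inconsistently; models missing a core
  residue or its C3′ are rejected at load with the residue named.
* The CLANS attraction is `1 - d/threshold`: the original tool only
  requires precomputed pairwise attractions, and any strictly decreasing
  map yields the same graph topology; the linear one makes the numbers
  interpretable. Example thresholds of 6 Å and 9 Å correspond to
  compact and open ensembles respectively.
* The stopping thresholds use ceilings (`ceiling(n/6)`,
  `ceiling(n/2)`), making the integer rule unambiguous for any `n`.
* The distance matrix is stored dense and written at 3-decimal
  precision; pools of 500–1000 models are tiny by linear-algebra
  standards, and text keeps artifacts diffable.

## Problem sizes in the test suite

The suite exercises superposition against a rotation-parameterization
optimizer on point sets of 3–50 atoms; clustering against an exhaustive
greedy re-implementation on 60-model matrices; and the full pipeline on
generated fixtures of 3 homologs × 10 decoys (unit tests) and 5
homologs × 100 decoys over five seeds (planted-partition recovery, with
adjusted Rand index ≥ 0.99 and correct target selection required in at
least four of five seeds). These sizes were chosen to mirror the
published operating point of ~500 pooled structures while keeping the
suite fast enough to run habitually.

## Known limitations

* The conserved-core definition requires a sensible alignment; heavily
  gapped families produce short cores, and core RMSD over very few
  residues is a weak signal (a minimum of ~8 core residues is enforced
  in the generator but not in the pipeline proper).
* One atom per residue ignores base orientation: mirror-image-like
  arrangements with similar C3′ traces are not distinguished.
* The greedy medoid capture assigns only the medoid's direct neighbors
  per round, so marginal models near the cutoff boundary can end up as
  singletons even when a human would assign them to the adjacent
  cluster.
* The geometric interaction detector is intentionally minimal; for
  publication-grade INF values, supply annotated interactions from a
  dedicated classifier as TSV.
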
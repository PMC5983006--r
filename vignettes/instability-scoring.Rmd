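---
title: "Scoring phylogenetic instability: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring phylogenetic instability: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloinstab)
```

# The problem

A gene family sampled across several species carries two superimposed
histories: the species phylogeny, and the family's own record of
duplications, losses and incongruence. Families under pressure to
diversify — typically those sampling the environment — accumulate
lineage-specific expansions and contractions; conserved endogenous
families track the species tree with one-to-one orthology. `phyloinstab`
turns this contrast into a number per gene: it reconciles the gene tree
with the species tree, partitions the gene tree into minimum instability
groups (MIGs), and assigns each MIG (hence each member gene) an
instability score.

# Event model

The gene tree must be rooted and binary; the species tree is topology-only
and may contain polytomies. Each gene-tree node is mapped to the species
tree by LCA mapping: a leaf maps to its assigned species, an internal node
to the LCA of its children's mappings. An internal node `g` is then
classified:

* **speciation** when `M(g)` differs from both children's mappings;
* otherwise the node is an *apparent duplication* (`M(g)` equals at least
  one child's mapping), resolved by the species sets of its two child
  clades: an **overlap** proves at least two copies co-existed in one
  species, so the node is a **duplication**; **disjoint** sets admit a
  single-locus explanation through incomplete lineage sorting,
  tree-estimation error or selection, so the node is one
  **incongruence** event.

Losses are charged only at duplication nodes, as the number of
species-tree edges between `M(g)` and each child's mapping — copies that
must have existed and then disappeared on those lineages. Speciation and
incongruence nodes charge no losses: charging hidden losses along every
speciation edge (as strict duplication–loss reconcilers do) would make the
score grade assembly gaps and missing annotations as heavily as real
contractions, and incongruence is deliberately allowed anywhere in the
tree rather than only at polytomies. Horizontal transfer is not modelled;
in multicellular gene families it is rare enough that the incongruence
event absorbs the occasional case.

# The score and its weights

For a MIG rooted at `g`,
`score(g) = θ_D·D(g) + θ_I·I(g) + θ_L·L(g) + θ_P·P(g)`,
with counts taken over all nodes at or below `g`. The defaults
`(θ_D, θ_L, θ_I, θ_P) = (1, 1, 0.5, 1)` weight a duplication and a loss
equally, an incongruence half as much (a single topological conflict is
weaker evidence of instability than a demonstrated extra copy), and give
the spread term the same leverage as one duplication. All four weights are
exposed (`instability_weights()`); scaling all of them by `c > 0` provably
leaves the partition unchanged and scales every score by `c`, so only
their ratios matter.

# Two-phase clustering

Every node is visited in depth-first post-order and two options are
priced: **merge** the node's whole clade into a single MIG, at the clade's
event cost, or let the children's partitions **remain**, at the sum of
their optima plus one `θ_D`. The surcharge is the key design choice: two
sibling MIGs assert two distinct loci in the parent, i.e. at least one
duplication somewhere above the clade that the event counts never see.
Pricing that unobserved duplication at `θ_D` makes merging win near the
leaves and remain take over exactly where the event record becomes too
expensive to absorb — and gives the dynamic program a clean global
guarantee: the returned partition minimises
`Σ_MIG eventcost(MIG) + θ_D·(#MIGs − 1)` over *all* partitions of the tree
into disjoint clades (each remain decision contributes one surcharge, and
a partition with k MIGs contains exactly k − 1 remain nodes). Ties are
broken toward merging, so the coarsest optimal clustering is returned and
results are deterministic. Events on nodes lying between MIG roots are
charged to no MIG; the surcharge subsumes them.

Phase 1 ignores branch lengths entirely (`P ≡ 0`). Phase 2 re-runs the
same program with the full score: each candidate clade's merge cost gains
`θ_P·P(clade)`. This penalises absorbing a sequence separated from its
nearest MIG by an unusually long path, and rewards tight clusters (P may
be negative, making the phase-2 objective and final scores negative for
compact, event-free MIGs — reported as-is, not floored, since the sign
carries information about below-median spread).

## Spread, MDS and degenerate cases

Spread needs coordinates, so the tree is embedded by classical (Torgerson)
MDS of the patristic distance matrix (`stats::cmdscale` underneath). All
axes with eigenvalue above `1e-9` of the largest are kept rather than a
fixed 2-D or 3-D projection: tree metrics are generally non-Euclidean, and
truncating at a fixed dimension would add avoidable distortion on top of
the genuinely negative eigenvalues. `σ(g)` is the root-mean-square
distance of the MIG's points from their centroid — the total standard
deviation, chosen because it is dimension-independent and satisfies the
checkable identity `σ² = Σ_ij d_ij²/(2n²)` on any embedded point set.
`σ̄` is the median σ over MIGs with ≥ 2 members; singletons are excluded
from the median and get `P = 0` (not −1, which would subsidise
fragmentation into singletons). If no non-singleton MIG exists or
`σ̄ = 0`, every P is 0 and the spread term is inert.

During refinement `σ̄` is computed once from the phase-1 partition and
held fixed — letting it float with the candidate partition would make the
objective self-referential. Final reported scores recompute `σ̄` from the
final partition. A lone phase-1 MIG is its own median (`P = 0`), so
refinement can only split it through the negative spread of its
sub-clades, which is exactly the long-branch behaviour wanted.

## Rooting

Unrooted input (the usual maximum-likelihood output) is rooted by scoring
every edge: each candidate rooting is reconciled and the one minimising
the phase-1 objective wins, with ties broken by the lexicographically
smallest sorted leaf set of the root's first child. The split edge's
length is shared equally between the two root children. Pass
`rooted = TRUE` to keep a tree that is already binary-rooted.

# Group comparison

`mann_whitney_one_tailed()` compares two sets of MIG scores with
`U = #{x > y} + 0.5·#{ties}`, so `U < n1·n2/2` means group 1 tends to be
smaller. For `n1·n2 ≤ 400` the p-value is the exact permutation
probability, computed by the shift-algorithm recursion over mid-ranks
(identical to enumerating all subsets, and valid under ties); larger
problems use the normal approximation with tie and continuity corrections,
which agrees with the exact p to well under 0.05 already at `n1, n2 ≤ 8`.
Normality screening is left to the user.

# The simulator

`simulate_family()` generates fixtures with known ground truth: one
ancestral gene descends a binary species tree; on each branch every copy
duplicates once with probability `dup_rate` and each resulting copy is
lost with probability `loss_rate`; surviving copies speciate at every
species-tree node. Incongruence is then injected at surviving speciation
nodes with probability `incong_rate` as a nearest-neighbour interchange
that swaps one child with the node's sibling — regrafting a lineage next
to its species-tree "uncle", the topological signature the classifier
looks for — rather than via an explicit coalescent, keeping the generator
deterministic, desk-scale and exactly labelled. Extinct families are
retried (the retries consume seeded draws, so a given seed is still fully
reproducible). Branch lengths are log-normal (terminal edges
`meanlog log(0.1), sdlog 0.3`; internal edges `meanlog log(0.05),
sdlog 0.2`), roughly the substitutions-per-site scale of a moderately
diverged protein family.

Defaults (`dup_rate = 0.2, loss_rate = 0.1, incong_rate = 0.05`) describe
a moderately unstable family; the parameter-recovery study uses a
6-species tree with `dup_rate` 0.5 in one two-species clade against 0.05
elsewhere, a realistic unstable-vs-stable contrast. Duplication rates may
vary per species-tree branch (named vector, `.default` fallback).

What the simulator does *not* emulate: sequence-level noise and
tree-estimation error, coalescent-correct ILS branch lengths, gene
conversion, and assembly artefacts. Passing tests therefore demonstrate
that the algorithm recovers the events its model defines, on trees whose
topology is exactly the event record — not that real trees are inferred
without error. The two published regression analyses (nematode collagens,
vertebrate Cyps) exercise real data and run whenever their deposited
input files are present under `inst/extdata/deposited/`.

# Verification and problem sizes

The clustering dynamic program is checked against brute-force enumeration
of every clade partition (both phases, refinement under the fixed `σ̄`),
on 200 simulated families capped at 12 leaves — small enough that
enumeration is exact and fast, large enough to cover duplications, losses
and incongruence jointly. The U statistic's exact p is checked against
literal `combn()` enumeration at `n1, n2 ≤ 8`, and against
`stats::wilcox.test` in the tie-free exact and large-sample normal
regimes. The duplication process is checked against an independent
copy-count Monte-Carlo (1,000 simulated families vs 20,000 oracle draws,
means within 10%). Parameter recovery uses 25 seeded replicates; the
Spearman correlation between per-MIG true event counts and assigned
scores is required to reach 0.8 and sits near 0.9–0.97 across seeds.
These sizes keep the full suite in the tens of seconds while leaving every
check exact or tightly bounded.

# Known limitations

* The method trusts the input gene tree; bootstrap or other uncertainty is
  not propagated, so poorly supported branches can masquerade as events.
* Losses are invisible where no duplication witnesses them, and the truth
  labels of the simulator count only events that survive to the output
  tree (a duplication whose one copy went extinct is reported in the raw
  counters but leaves no node).
* Incongruence is a catch-all: ILS, hidden paralogy and artefacts are not
  distinguished.
* Scores are comparable within one analysis, not across gene families
  with different σ̄ or tree depths.
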
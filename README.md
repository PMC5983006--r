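# phyloinstab

Quantify the phylogenetic instability of the members of a multi-species
gene family.

Gene families that interact directly with the environment — detoxification
enzymes, chemosensory receptors, immune and structural proteins — tend to
evolve by repeated lineage-specific duplication and loss, leaving a gene
tree that disagrees with the species tree. Families with conserved
endogenous roles instead show clean one-to-one orthology. `phyloinstab`
takes a gene-family tree and the species relationships, reconciles them,
partitions the gene tree into **minimum instability groups (MIGs)** —
clades that most parsimoniously descend from a single ancestral locus —
and gives every gene an **instability score**. High-scoring MIGs are
candidates for adaptive, environment-facing roles; low-scoring MIGs
suggest conserved function. The package is agnostic to how the input tree
was built (nucleotides, amino acids, k-mer distances, ...).

## The model

Each internal node of the rooted binary gene tree is mapped to the species
tree by LCA mapping and classified as one gene event:

* **speciation** — the node's mapping differs from both children's mappings;
* **duplication** — an apparent duplication whose child clades share at
  least one species (two copies provably co-existed); **losses** are charged
  here as the species-tree edge distance from the node's mapping to each
  child's mapping;
* **incongruence** — an apparent duplication whose child clades have
  disjoint species sets, explainable by incomplete lineage sorting,
  tree-estimation error or selection, charged as a single event.

A MIG rooted at node *g* scores

```
score(g) = θ_D·D(g) + θ_I·I(g) + θ_L·L(g) + θ_P·P(g)
```

where D, I, L count the events at or below *g*, and P(g) = σ(g)/σ̄ − 1 is
the **relative spread**: σ(g) is the standard deviation of the MIG's
points in a classical-MDS embedding of the patristic distance matrix, and
σ̄ the median σ over non-singleton MIGs. Default weights are
(θ_D, θ_L, θ_I, θ_P) = (1, 1, 0.5, 1).

Clustering is a two-phase dynamic program over the gene tree. In
post-order, every node compares **merging** its whole clade into one MIG
(the clade's event cost) against letting the children's MIGs **remain**
(their optima plus one θ_D, the surcharge for positing one more ancestral
locus). Phase 1 ignores branch lengths (P ≡ 0); phase 2 repeats the
program with the full score function, using the σ̄ fixed from phase 1.
Both phases provably attain the global minimum of their objective over all
clade partitions.

## Worked example

```r
library(phyloinstab)

g <- parse_newick(
  "(((a1:0.12,a2:0.10):0.08,b1:0.15):0.06,((c1:0.11,d1:0.09):0.05,(e1:0.35,e2:0.30):0.07):0.04);")
info <- read_species_info(text =
  "[species tree]\n(((A,B),C),(D,E));\n[assignments]\nA: a*\nB: b1\nC: c1\nD: d1\nE: e*")
out <- run_pipeline(g, info, rooted = TRUE)
out$result$migs
#>   id size D I L     sigma          P      score
#> 1  1    3 1 0 0 0.1763204  0.0000000  1.0000000
#> 2  2    2 0 0 0 0.1000000 -0.4328507 -0.4328507
#> 3  3    2 1 0 0 0.3250000  0.8432352  1.8432352
```

Species A carries two copies (`a1`, `a2`): their MIG holds one duplication
and scores 1.0. The clean orthologs `c1`/`d1` form a tight, event-free MIG
whose below-median spread makes the score slightly negative. The `e1`/`e2`
pair is both duplicated and unusually spread out (long branches), so it
scores highest — the most unstable cluster in this family. Per-gene output
(every member of a MIG shares its score):

```r
cat(write_scores_csv(out$result$scores))
#> sequence,species,cluster,score
#> a1,A,1,1.0
#> a2,A,1,1.0
#> b1,B,1,1.0
#> c1,C,2,-0.43285070098192224
#> d1,D,2,-0.43285070098192224
#> e1,E,3,1.843235221808755
#> e2,E,3,1.843235221808755
```

To compare two sets of MIG scores (e.g. genes with vs without a knock-down
phenotype), `compare_mig_sets(a.txt, b.txt)` runs a one-tailed
Mann–Whitney U test with ties counted half, exact for small samples.

A command-line wrapper ships in `exec/phyloinstab`:

```sh
phyloinstab run gene.nwk info.txt -o scores.csv --migs migs.csv
phyloinstab simulate species.nwk --seed 7 --dup-rate 0.3 -o fam
phyloinstab compare withPheno.txt withoutPheno.txt
```

`simulate` generates gene families along a species tree with known
duplication/loss/incongruence events ([`simulate_family()`]), the ground
truth used throughout the test suite.

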
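# onenest

Reconstruction of uprooted 1-nested phylogenetic networks from circular
split systems.

## The problem

Reticulate evolution (hybridization, recombination, lateral transfer) is not
representable by a tree. *Uprooted phylogenetic networks* — connected
leaf-labeled graphs with no degree-2 vertices and no cycle shorter than
four — are a tractable generalization, and the *1-nested* ones (no two
cycles share an edge) have a complete combinatorial theory in terms of the
split system `Σ(N)` they display: the bipartitions `A|B` of the taxon set
induced by the (set-inclusion) minimal edge cuts of the network, each cut
being a cut edge or a pair of edges within one cycle.

This package implements that theory end to end, for people who want to work
with split systems directly rather than through distance-based heuristics:

* **Split systems** (`make_split`, `split_system`): canonical splits,
  compatibility (`are_compatible`), the incompatibility graph and its
  connected components (`incompatibility_components`), circular orderings,
  the maximal circular system `interval_splits`, and an exact, self-verifying
  circularity test `is_circular` that returns a witness ordering.
* **Closures** (`intersections`, `iota`, `intersection_closure`,
  `i_closure`): the intersection of splits `S₁, S₂` is
  `A₁∩A₂ | Ā₁∪Ā₂` over side choices with `A₁∩A₂ ≠ ∅`. Restricting to
  incompatible pairs gives the *I-intersection closure* `I(Σ)`, the key
  invariant: a split system containing all trivial splits equals `Σ(N)` for
  a 1-nested network `N` **iff** it is circular and I-intersection closed
  (the 1-nested analogue of the splits equivalence theorem), and `N` is then
  unique up to isomorphism and partial resolution.
* **Networks** (`uprooted_network`, `splits_of`, `validate_network`):
  split extraction with multiplicities (1, 2 or 3 = the number of distinct
  minimal cuts per split), partial resolution moves and their converses,
  canonical unresolved forms, and leaf-label-respecting isomorphism.
* **Buneman graphs** (`buneman_graph`, `buneman_blocks`, `gate`,
  `marguerite`, `embed_network`): the median network on all consistent
  side-selection maps, its blocks (one per incompatibility component), the
  gates, the marguerite subgraphs, and the embedding of a network into the
  Buneman graph of its own splits.
* **Reconstruction** (`minimal_1nested`, `network_from_buneman`,
  `buneman_tree`, `resolve_by_splits`): for any circular `Σ` with trivial
  splits, the 1-nested network displaying `Σ` with the *fewest* total
  splits, built in polynomial time from the incompatibility-component
  quotients — plus the independent Buneman-graph route used as a
  cross-check.
* **Synthetic data** (`random_1nested_network`, `random_circular_system`)
  and IO: plain-text and NEXUS SPLITS (SplitsTree4 dialect) files,
  GraphML/GML networks, and a command-line front end
  (`inst/cli/onenest.R`) with `simulate / extract / check / closure /
  build / buneman` subcommands.

## Worked example

The shipped fixture `example8.txt` holds a 17-split system on
`X = {1,…,8}`: the 8 trivial splits plus 81|234567, 78|123456, 781|23456,
234|56781, 34|567812, 345|67812, 2345|6781, 3456|7812 and 56|78123.

```r
library(onenest)
sigma <- read_splits(system.file("extdata", "example8.txt", package = "onenest"))
is_circular(sigma)
#> Circular ordering: 1 2 3 4 5 6 7 8
is_i_closed(sigma)
#> [1] TRUE
net <- minimal_1nested(sigma)
net
#> Uprooted network: 18 vertices, 19 edges, 8 leaves (1 2 3 4 5 6 7 8)
splits_of(net)
#> Split multiset: 17 distinct splits from 26 minimal cuts; multiplicities 1/2/3
splits_of(simple_level1_from_ordering(is_circular(sigma)))
#> Split multiset: 28 distinct splits from 36 minimal cuts; multiplicities 1/2
```

Reading the output: the system is circular (witness ordering `1 … 8`) and
I-intersection closed, so the optimal network displays *exactly* the 17
input splits — here a 4-cycle and a 5-cycle joined by a cut edge (that cut
edge's split, 781|23456, is induced by three distinct minimal cuts, hence
multiplicity 3). The naive construction — a single cycle through the
witness ordering — displays 28 = C(8,2) splits, 11 of them never asked
for; the reconstruction postulates none.

## Acceptance script

`scripts/acceptance.R` rebuilds the headline quantities from scratch with
the installed package: the size of the intersection set of a compatible
split pair on six taxa, and the maximum minimal-cut size over all splits of
a 4-cycle/6-cycle network, measured by exhaustive enumeration of edge
subsets and cross-checked against the structured cut-edge/cycle-pair
enumeration. Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
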
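---
title: "Split systems, closures and optimal 1-nested networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split systems, closures and optimal 1-nested networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onenest)
```

## The objects

A *split* of a finite taxon set $X$ ($n \ge 3$) is an unordered bipartition
$\{A, X-A\}$ with both sides nonempty; the package stores the side
containing the minimum taxon (labels compare in natural, numeric-aware
order), so every split has one canonical representative. Two distinct
splits are *compatible* when one of the four side intersections is empty —
equivalently, when some side of one strictly contains a side of the other.
We additionally define equal splits to be compatible, so that compatibility
of a whole system reduces to pairwise checks.

An *uprooted 1-nested network* is a simple connected graph with leaf set
$X$, no degree-2 vertices, all cycles of length at least four, and no two
cycles sharing an edge (every block is an edge or a cycle — a leaf-labeled
cactus). It displays the split system $\Sigma(N)$ of all bipartitions of
$X$ induced by minimal cuts: every cut edge, and every pair of distinct
edges within one cycle. The *multiplicity* of a displayed split is its
number of distinct minimal cuts; for 1-nested networks it is 1, 2 or 3
(3 exactly for a cut edge both of whose endpoints lie on cycles).

## The closure and the characterization

For distinct splits $S_1, S_2$ and side choices $A_1 \in S_1$,
$A_2 \in S_2$ with $A_1 \cap A_2 \neq \emptyset$, the *intersection* is the
split $A_1 \cap A_2 \mid \bar A_1 \cup \bar A_2$. A compatible pair has
exactly 3 intersections (including both inputs); an incompatible pair has
exactly 4, forming a compatible quartet that excludes both inputs — the
*I-intersection* $\iota(S_1, S_2)$. The *I-intersection closure*
$\mathcal I(\Sigma)$ is the least superset closed under $\iota$ on
incompatible pairs. It is a closure operator (extensive, idempotent,
monotone), is independent of the order in which pairs are processed, and
decomposes as the union of the closures of the connected components of the
incompatibility graph $\mathrm{Incomp}(\Sigma)$ — which the implementation
exploits by closing each component separately.

The central facts the package operationalizes:

* $\Sigma$ (containing all trivial splits) equals $\Sigma(N)$ for some
  1-nested $N$ **iff** $\Sigma$ is circular and I-intersection closed, and
  $N$ is then unique up to isomorphism and partial resolution.
* The closure of the adjacent-pair system of a circular ordering is the
  full interval-split system of that ordering, of size $n(n-1)/2$.
* $\mathcal I(\Sigma)$ of a circular $\Sigma$ is maximal circular iff
  every pair of taxa is separated by a nontrivial split of $\Sigma$ and
  $\mathrm{Incomp}$ of the nontrivial splits is connected. Both this
  two-condition test and the direct one (compare the closure against the
  interval splits of a witness ordering) are implemented and cross-checked.

## Reconstruction

`minimal_1nested()` builds, for a circular $\Sigma$ with trivial splits,
the 1-nested network displaying $\Sigma$ with the fewest total splits:

1. split $\Sigma$ into incompatibility components;
2. singleton components become cut edges of a backbone tree;
3. each component with $\ge 2$ splits is quotiented by the relation
   "agrees on every component split"; the I-closure of the quotient (capped
   at $m(m-1)/2$ for $m$ blocks — a bound no circular input can exceed)
   must be maximal circular, and its 2-splits spell out the unique
   Hamiltonian cycle of the blocks;
4. the union of the cut-edge splits, the per-cycle block splits and the
   trivial splits is compatible exactly when the input was circular; its
   unique tree is built by the laminar-hierarchy construction rooted at the
   minimum taxon;
5. each placeholder vertex (the tree vertex whose removal induces a
   component's block partition) is expanded into its cycle in block order.

The result is verified to display $\Sigma$ before it is returned, which
makes the constructive route of `is_circular()` sound: a verified witness
ordering is read off the built network by an Euler-style traversal
(`leaf_ordering()`), and any failure along the way reports non-circularity.

`network_from_buneman()` is the second, independent route: enumerate the
Buneman graph $G(\Sigma)$ (all side-selection maps with pairwise
intersecting images; edges at symmetric difference one), locate its blocks
via the bijection with incompatibility components, take each block's gates
(the gates of the Kuratowski maps), wire them into a cycle and delete the
block interiors. The two routes are compared network-by-network in the
test suite; agreement of two algorithmically unrelated constructions of a
provably unique object is the package's strongest internal check.

### Design choices made where the design was open

* **Cyclic order of the gates.** Within a block, the cyclic order of the
  gates is recovered as the circular ordering of the gate set under which
  every component split, restricted to the gates, is an interval — found by
  the exact exhaustive ordering search. A nearest-neighbour rule in the
  graph metric is correct for maximal circular systems but fails for
  sub-maximal ones, so it is not used.
* **Embedding a network into its Buneman graph.** A vertex on a cycle is
  mapped to the gate of a reference taxon's Kuratowski map *in the block of
  the cycle's unique multi-member incompatibility component*, not in the
  full nontrivial cycle system: an m-split that doubles as a cut-edge split
  lives in its own singleton component, and including it would merge the
  images of a partially resolved cycle vertex and its attachment vertex.
  With the component form the map is a bijection onto the gates, which the
  tests verify on fixtures.
* **Equal splits are compatible** (see above); **empty systems are
  rejected** except by explicit internal constructors.
* **$n = 3$ degenerates**: cycles need length 4, so the simple network of
  an ordering on 3 taxa is the star tree, every system on 3 taxa is
  compatible, and the unique maximal circular system is the 3 trivial
  splits (the two-condition maximality test special-cases this).
* **Canonical forms.** Circular orderings canonicalize by rotation to the
  minimum taxon and reflection so the second element precedes the last;
  split systems sort canonically by split size then lexicographic key.
  Networks canonicalize up to partial resolution by exhaustively
  contracting (i) cut edges between two cycle vertices and (ii) cut edges
  from a degree-3 cycle vertex to an interior tree vertex; the fixpoint is
  order-independent because a contraction never creates new eligible edges
  at other vertices.
* **Caps.** The Buneman enumeration refuses more than 25 splits by default
  (the vertex set can be exponential); closures cap at $2^{n-1}-1$ splits
  ($10n^2$ for $n > 16$) and return a `truncated` flag rather than failing.
  The exhaustive circularity search is used up to $n = 7$ ($\le 360$
  canonical orderings), the constructive route beyond, with a brute-force
  fallback up to $n = 10$ when construction fails.

## The synthetic generator

`random_1nested_network()` emulates the combinatorial shape of desk-scale
reticulate phylogenies: a uniform random leaf-addition binary tree, into
which the requested number of cycles is carved by contracting a connected
cluster of $L-2$ interior vertices and blowing the cluster up into a cycle
of length $L$ (lengths drawn uniformly from 4–6 by default — cycles much
longer than that are rare in level-1 analyses and would dominate small
taxon sets). Attachments are then contracted back onto their cycles
independently with probability $1 - $ `resolve_probability` (default 0.5,
an uninformative midpoint) to produce partially unresolved variants.
Infeasible requests (no interior cluster large enough) raise an error
rather than silently degrading. All randomness flows from one seeded
stream, so identical arguments and seed give byte-identical GraphML.

`random_circular_system()` draws a uniform random circular ordering and
keeps each nontrivial interval split independently with probability
`subsample_fraction` (default 0.5), always keeping the trivial splits.
The output is circular *by construction* — so a green circularity test on
generated data establishes correctness of the witness checker, not of the
search; the search itself is exercised against non-circular fixtures and
the exhaustive method. Neither generator emulates noise in estimated
splits, weights, or missing trivial splits; real data filtered from
distance or sequence analyses may be non-circular, which the tools report
rather than repair.

Test scale is deliberately desk-sized (taxa 5–10, 0–3 cycles, 50 round
trips and 25 route agreements under fixed seeds) to keep the default suite
fast; every property asserted is exact, not approximate, so scale buys
coverage of shapes, not statistical power.

## Known limitations

* Splits are unweighted throughout; there is no split-weight fitting and
  no ordering inference from distances (use NeighborNet-style tools for
  that, then feed the splits in).
* Minimal-cut extraction is implemented for 1-nested networks only; the
  general minimal-cut enumeration exists solely as the brute-force oracle
  used in tests.
* The Buneman enumeration is exponential in the number of splits and
  guarded by a cap; the marguerite constructor is exact but intended for
  $k \lesssim 10$.
* Optimality of the reconstruction is among 1-nested networks; nothing is
  claimed relative to level-2 or general networks.
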
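---
title: "Ranked supertree synthesis: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranked supertree synthesis: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthtree)
```

## The problem

A comprehensive taxonomy covers all taxa but encodes little phylogenetic
signal; published phylogenies are well-resolved but cover small, patchy,
overlapping leaf sets and disagree with each other. `synthtree` merges a
rooted taxonomy and an ordered (ranked) collection of rooted trees into one
summary supertree that

1. displays no grouping unsupported by an input edge,
2. defers to the higher-ranked tree wherever inputs conflict,
3. contains no unnecessary polytomies (every omitted input grouping
   conflicts with something that was kept), and
4. greedily displays as many input groupings as the ranking allows.

This is a summarization method, not a phylogeny estimator: conflicts are
resolved by curated ranks, never by weighing evidence, and the annotation
document exists precisely so that users can see which inputs support or
contradict every summary node.

## The rooted-split calculus

Cutting an edge of a rooted tree bi-partitions its leaves into the cluster
(include side) and the root side (exclude). Because the root side always
contains the root, two splits conflict only when all three of
`A1∩B1`, `A1∩B2`, `A2∩B1` are non-empty -- the fourth cell is never
tested. Split `A` displays `B` when `B1 ⊆ A1` and `B2 ⊆ A2`; a tree
displays a split when some edge does; an edge is *supported* when
contracting it stops some input split from being displayed. Two splits are
compatible exactly when some rooted tree displays both; the test suite
verifies this equivalence exhaustively against enumeration of all 105
rooted binary shapes on five leaves.

Splits with fewer than two included leaves or an empty exclude set carry no
grouping information (a two-leaf tree says nothing) and are excluded from
all compatibility bookkeeping.

## Pipeline stages

**Taxonomy cleaning.** Taxa flagged as questionable (e.g. `unplaced`,
`barren`) are pruned with their subtrees; the flag list is part of the run
configuration, not hard-coded. A pruned id subsequently behaves like an
invalid id. Stale ids are chased through the forwarding table.

**Input cleaning.** Each raw tree is pruned to its curated ingroup (the
outgroup's branching is untrustworthy by construction), unmapped tips are
dropped, forwarded ids updated, and tips are made unique and pairwise
non-nested: the tip mapped to the higher taxon loses against a tip mapped
inside it, and among duplicates the curator's exemplar wins, falling back
to the lexicographically lowest original tip identifier -- arbitrary but
repeatable. Trees left with fewer than three leaves carry no grouping
information and are excluded (but logged).

**Exemplification.** A tip mapped to a genus or family is ambiguous, so
every higher-taxon tip is replaced by the union of its terminal descendants
sampled anywhere in the input set (one deterministic arbitrary terminal --
the smallest uid -- if none). The exemplars are attached as children of the
former tip's parent, i.e. the tip edge is collapsed, so no monophyly claim
sneaks in: `((A,B),c)` becomes `((a1,a2,b1,b2),c)`. The same map is applied
to every tree. The taxonomy is then pruned to the sampled terminals
(monotypic containers are kept as degree-two nodes); everything pruned here
is grafted back after solving.

**Decomposition at uncontested taxa.** A tree *contests* a taxon when no
resolution of the tree's polytomies could make the taxon monophyletic --
polytomies are soft, so a taxon is not contested merely because it is not
displayed. Taxa contested by nothing are safe cut points: each becomes the
root of a subproblem whose tips are the next slice points and terminals
below it, with every relevant input tree sliced accordingly. Slicing is
only correct because of the purity lemma: at the MRCA of an uncontested
taxon's tips, every child subtree is entirely inside or outside the taxon.
A taxon whose slice would have a single leaf is not used as a cut point;
its chain is reinstated at the unpruning step. Decomposition is a
performance device with a curation lever: adding any tree that contests a
taxon dissolves that constraint in the next run.

**Solving.** Within a subproblem, splits are offered in rank order --
input trees first, taxonomy last, and within a tree in one fixed post-order
traversal (children before parents, left to right as parsed). A candidate
is accepted iff the accepted set plus the candidate is jointly displayable,
decided by a BUILD algorithm generalized from rooted triplets to whole
rooted splits: at each recursion level the include sets of the active
splits are connected in a union–find graph, connected components become
children, and a single component with an active split means incompatible.
With triplet inputs this is exactly the classic algorithm, and with larger
splits the outcome equals full triplet decomposition (tested against an
independent triplet implementation). Compatibility is decided by a full
re-run per candidate: semantics first, incremental maintenance would be an
optimization with no behavioural difference. The final tree is built from
the accepted set, so every edge is supported and every polytomy is forced:
each rejected split conflicts with the accepted set, which is what makes
every exclusion reportable.

Acceptance within a single tree is order-invariant (a tree is
self-compatible); the traversal choice can only affect which of several
same-tree splits is *blamed* for a later conflict.

**Grafting, unpruning, naming.** Non-root subproblem roots appear as a leaf
in exactly one other subproblem; grafting merges nodes with equal taxon
labels. Unsampled taxa are then reattached: a taxon whose sampled
descendants form a cluster of the grafted tree gets its unsampled children
there, with nested monotypic containers reinstated as named degree-two
nodes; a *broken* taxon (one that conflicts with the grafted tree) has no
node, and its unsampled children attach at the MRCA of its sampled
children. The alternative -- attaching at the least inclusive unbroken
ancestor -- is available as `broken_attach = "ancestor"` but not default,
because adjacent broken taxa then pile enormous polytomies deep in the
tree. When a broken taxon has a single sampled child whose own node *is*
the MRCA, the unsampled children attach one level up, as its siblings;
nesting them inside the sampled child would assert structure no input
implies. Finally every node is named: `ottX` when its cluster equals a
taxon's cluster (least inclusive taxon first along monotypic chains),
otherwise `mrcaottX1ottX2` with `X1` the smallest descendant id and `X2`
the smallest id that pins the node as the MRCA -- a labelling invariant
under branch rotation and biased toward ids likely to survive taxonomy
updates.

**Annotation.** For every input tree the summary is restricted to the
input's leaves, keeping degree-one chains (the induced tree). An input edge
displayed along a single-node path yields `supported_by`; along a
multi-node path, `partial_path_of` for each node on it; tip paths yield
`terminal`. Conflicting input edges are listed under `conflicts_with` of
every summary node whose restricted split they conflict with (all of them,
not a minimal set). `resolves` records summary nodes that refine an input
polytomy, and `resolved_by` the reverse -- input nodes that could refine a
summary polytomy compatibly. Because the solver leaves no unnecessary
polytomy, annotating a synthesis against its own inputs yields zero
`resolved_by` entries, which the tests assert on every generated fixture.

## The reliability round trip

Splitting the summary at every taxonomy-labelled node yields slices with a
taxonomy node at the root, taxonomy nodes or terminals at the tips and
none internally; internal-taxon tips are then replaced by a terminal
representative (smallest uid). Re-synthesizing from these slices plus the
same taxonomy reproduces the summary exactly; taxa contested in the
original run stay contested because their conflicting structure lies
strictly inside one slice. The suite asserts exact reproduction on 50
generated runs.

## What the generator emulates (and what it does not)

`generate_fixture()` builds a random bushy taxonomy with a couple of
flagged (prunable) subtrees and forwarding entries, draws one fully
resolved "true" refinement of it, and derives each ranked input tree from
that truth by leaf subsampling, SPR perturbation (the source of genuine
conflict and contested taxa), random edge collapse into soft polytomies,
relabelling of tips to higher taxa, duplicate/stale/unmapped tips, and
occasional outgroups with an ingroup annotation. Defaults
(`n_taxa = 32`, `n_trees = 5`, `leaf_sampling_prob = 0.6`,
`polytomy_prob = 0.2`, `n_spr_moves = 1`, `higher_taxon_tip_prob = 0.15`,
`outgroup_prob = 0.3`) describe a corpus in which trees overlap
substantially and disagree occasionally -- the regime the method is
designed for.

A single underlying truth per fixture is deliberate: without it,
independently randomized resolutions of the same taxonomy polytomy would
manufacture conflict between every pair of trees, which real curated
corpora do not exhibit. What the generator does *not* emulate: thousands of
trees with nearly disjoint leaf sets, rank ties, heavily non-monophyletic
taxonomies, or label noise beyond the forwarding table -- so green tests
demonstrate the method's guarantees under these conditions, not
performance on any particular empirical corpus.

Test problem sizes (up to 64 taxa and 8 trees per fixture, 100 fixtures
for the guarantee battery, 50 for the round trip) were chosen so the whole
suite exercises every stage many times while staying comfortably
interactive.

## Numerical and degenerate-input choices

* All tie-breaks (duplicate tips, arbitrary exemplars, sibling attachment
  order) use lexicographic or numeric uid order, making every artifact
  byte-stable across reruns.
* A subproblem whose universe is a single leaf (a degenerate root slice)
  is solved as a labelled degree-two chain by the same code path.
* Degree-two chains are first-class: taxonomy containers survive pruning,
  grafting and naming, and the support check treats their edges as
  taxonomy semantics rather than phylogenetic groupings.
* `INCOMPATIBLE` is represented as `NULL` from `build_compatible()`; the
  greedy driver never returns it for the accepted set (a self-compatible
  set is always buildable).
* Newick dialect: unquoted labels, literal underscores, branch lengths
  parsed and discarded, one tree per line. Duplicate tips are a parse
  error except on the explicit cleaning path that exists to remove them.

## Known limitations

* Ranks are per-tree; edge-level confidence (bootstrap, posterior) is
  ignored by design.
* The greedy ranked incorporation is a heuristic for the weighted
  display-maximization ideal; decomposition at uncontested taxa can
  additionally cost jointly-optimal solutions when trees contest a taxon
  only in combination.
* Conflict resolution quality is entirely the curator's ranking; the
  method guarantees transparency, not accuracy.
* The solver re-runs BUILD per candidate split (quadratic-ish per
  subproblem); this is fine at the subproblem sizes decomposition
  produces, and the kernel is compiled, but a persistent-forest
  implementation would be needed for pathological undecomposable inputs.
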
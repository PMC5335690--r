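# synthtree

Ranked supertree synthesis: merge a comprehensive rooted taxonomy and an
ordered collection of rooted phylogenies into one summary supertree, with a
provenance annotation for every summary node.

## Who this is for

Projects that summarize many published phylogenies over a reference
taxonomy — where the taxonomy supplies complete coverage, individual trees
supply resolution for overlapping subsets of taxa, and disagreements must
be settled transparently by a curated ranking rather than by hidden
weighting. The output is a summary of the inputs, not an estimate of the
true tree.

## The method in brief

Cutting edge *j* of a rooted tree yields a rooted split
*S₁(j) |• S₂(j)*: the cluster *S₁* away from the root and the root side
*S₂*, which implicitly contains the root. Split *A* **displays** *B* when
*B₁ ⊆ A₁* and *B₂ ⊆ A₂*; *A* and *B* **conflict** when all of
*A₁∩B₁*, *A₁∩B₂*, *A₂∩B₁* are non-empty (the root-side cell is never
tested); two splits are compatible exactly when some rooted tree displays
both. An edge of the summary 𝕊 is **supported** by input edge *j* when
contracting it would stop 𝕊 from displaying *j*.

The pipeline: prune flagged taxa from the taxonomy; clean each input tree
(ingroup, unmapped/stale/duplicate/nested tips); replace higher-taxon tips
by shared terminal exemplars without introducing monophyly claims; cut the
problem into subproblems at taxa contested by no input (soft-polytomy
semantics); within each subproblem greedily accept splits in rank order —
taxonomy last — using a BUILD algorithm generalized from rooted triplets to
rooted splits; graft the subproblem solutions; reattach taxonomy-only taxa
(children of *broken* taxa go to the MRCA of the taxon's sampled
children); name every node (`ottX` for taxon clusters, `mrcaottX1ottX2`
otherwise); and annotate every summary node with the input nodes that
support it (`supported_by`, `partial_path_of`, `terminal`), conflict with
it (`conflicts_with`), or relate to it by polytomy refinement (`resolves`,
`resolved_by`). The guarantees: no unsupported edges, rank-1 groupings
always displayed, every omitted input grouping in conflict with the
summary, and no unnecessary polytomies (zero `resolved_by` against the
run's own inputs).

## Worked example

```r
library(synthtree)

fx  <- generate_fixture(n_taxa = 12, n_trees = 3, seed = 42)
res <- run_synthesis(list(taxonomy    = fx$taxonomy,
                          trees       = fx$trees,
                          prune_flags = fx$prune_flags))
print(res)
#> supertree synthesis: 12 leaves
#>   subproblems: 3 (trivial by tips: 1 , by trees: 1 ); largest: 7 tips
#>   input splits: supported_by 6 partial_path_of 1 conflicts_with 4 resolved_by 0
```

Twelve terminal taxa synthesize into a tree built from 3 subproblems (one
is trivially small). Six input groupings are displayed by exactly one
summary edge each, one along a multi-edge path, four conflict with the
summary and were excluded, and no summary polytomy could be resolved by any
input — the no-unnecessary-polytomies guarantee. Every exclusion is
attributable:

```r
res$rejections
#>    subproblem rank  tree_id node_id   reason
#> 6       ott30    3    tree3  node22 conflict
#> 7       ott30    3    tree3   ott40 conflict
#> ...
#> 14      ott30    4 taxonomy   ott90 conflict
```

tree3 ranks below tree1 and tree2, so four of its groupings (and two
taxonomy groupings, e.g. the taxon `ott40` broken by better-ranked trees)
lost to conflict. The summary itself carries stable node names:

```r
res$labelled
#> rooted_tree: 12 leaves, 23 nodes
#> ((ott50,(ott70,(ott160,ott200)mrcaott160ott200)ott150)mrcaott50ott70,...
```

Slicing the summary at taxonomy nodes and re-synthesizing reproduces it
exactly:

```r
roundtrip_check(res)$identical
#> [1] TRUE
```

Real inputs load the same way: `load_taxonomy("taxonomy.tsv",
"forwards.tsv")` (OTT-style tab-pipe-tab dialect), `read_newick()` for
tree files, and `run_synthesis()` accepts a YAML config naming the files,
flags and output directory, writing every staged artifact
(`cleaned_ott/ … annotated_supertree/`). A thin CLI covering run-all,
make-fixture and roundtrip-check lives at `inst/scripts/synthtree`.

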
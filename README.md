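# ragcut

Spectral partitioning of coarse-grained RNA tree graphs.

## The problem

RNA structure is modular: helices alternate with hairpin loops, internal
loops/bulges, junctions, and exterior strands, and large structures are
built from recurring motifs. The RNA-As-Graphs (RAG) tree representation
collapses a pseudoknot-free secondary structure to a small unrooted tree —
helices become edges, single-stranded elements become vertices, labeled in
5′→3′ order — which makes the modularity question a graph-partitioning
question. `ragcut` is for structural bioinformaticians and RNA designers
who want to

* split an RNA tree graph into two topologically meaningful subgraphs,
* decompose a large graph recursively into minimal modules (hairpin stems
  and k-way junctions) and obtain the inverse hierarchical assembly plan,
* name and look up tree topologies in a connectivity-ordered catalog, and
* convert dot-bracket / CT / BPSEQ secondary structures into tree graphs.

## The method

For a tree *G* = (*V*, *E*), the Laplacian is *L* = *D* − *A* (degree
matrix minus adjacency matrix). Its eigenvalues satisfy
0 = λ₁ ≤ λ₂ ≤ … ≤ λₙ; λ₂, the algebraic connectivity, is positive for
connected graphs and grows with compactness. The eigenvector µ₂ for λ₂
(the Fiedler vector) has components νᵢ that sum to zero and encode each
vertex's topological position. A bisection thresholds at a splitting value
*s*: part A = {i : νᵢ ≤ s}. Three choices of *s* give the three cuts:

| cut | *s* | behavior |
|---|---|---|
| median | median of νᵢ | two equal-sized halves, may break junctions |
| sign | 0 | separates negative from positive components |
| gap | midpoint of the largest gap in the sorted νᵢ | separates topologically distinct subgraphs; keeps junctions intact |

The gap cut, applied recursively with an *overlap* extraction rule (the cut
helix stays in one fragment together with a duplicated endpoint, so the two
fragments share exactly one vertex), decomposes a graph into star-shaped
minimal modules and yields an assembly plan by reading the cuts in reverse.

## Worked example

```r
library(ragcut)

g <- read_edgelist(system.file("extdata", "6_5.edgelist", package = "ragcut"))
glance(rag_spectrum(g))
#> # A tibble: 1 × 4
#>       n n_edges lambda2 degenerate
#>   <int>   <int>   <dbl> <lgl>
#> 1     6       5   0.486 FALSE

gap_cut(g)
#> <rag_cut> method = gap, s = -0.107
#>   parts: {4,5} / {1,2,3,6}
#>   cut edges: 2-4
#>   gap width: 0.5379
```

λ₂ = 0.486 rounds to the recorded 0.49 for this 4-way-branched topology
(`6_5`, RNase P), and the gap cut separates its 2-vertex linear arm {4,5}
from the 4-way junction {1,2,3,6} by severing the one helix (edge 2-4)
between them.

Decomposing the 10-vertex glycine-riboswitch topology `10_19` by its
recorded splits and inverting the cuts:

```r
fx <- rag_example("10_19")
pt <- replay_splits(fx$graph, fx$recorded_splits)
pt
#> <rag_partition> mode = overlap, depth = 3, 5 leaves
#>   leaf {1,2,3,5}
#>   leaf {3,4}
#>   leaf {1,6,7,8}
#>   leaf {8,9}
#>   leaf {9,10}

assembly_plan(pt, catalog = rag_catalog(10))[
  , c("step", "shared_vertex", "left_id", "right_id", "product_id")]
#>   step shared_vertex left_id right_id product_id
#> 1    1             8     4_2      2_1        5_2
#> 2    2             9     5_2      2_1        6_2
#> 3    3             3     4_2      2_1        5_2
#> 4    4             1     5_2      6_2      10_19
```

Five minimal modules result — three hairpins (`2_1`) and two 3-way
junctions (`4_2`) — and the plan reads bottom-up: junctions are joined to
their neighboring stems first (merge through shared vertex 8, then 9, then
3), and the two halves unite last through vertex 1 to rebuild `10_19`.
`assemble(pt)` executes the plan and returns the root graph exactly.

Topology catalogs are connectivity-ordered tibbles:

```r
rag_catalog(4)
#> # A tibble: 4 × 6
#>   rag_id     n     k lambda2 canonical edges
#>   <chr>  <int> <int>   <dbl> <chr>     <list>
#> 1 2_1        2     1   2     (())      <int [1 × 2]>
#> 2 3_1        3     1   1     (()())    <int [2 × 2]>
#> 3 4_1        4     1   0.586 ((())())  <int [3 × 2]>
#> 4 4_2        4     2   1     (()()())  <int [3 × 2]>
```

Secondary structures convert directly: `to_rag_tree("((((....))))")` gives
the two-vertex hairpin graph `2_1`.

A thin command-line interface over the same functions lives at
`inst/cli/ragcut.R` (subcommands `spectrum`, `cut`, `decompose`,
`enumerate`, `identify`, `convert`, `fixtures`), e.g.
`Rscript inst/cli/ragcut.R cut graph.edgelist --method gap --json`.

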
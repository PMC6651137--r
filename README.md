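# ndprio

Network-diffusion prioritization of disease genes from multi-layer omics
evidence.

Complex disorders rarely map onto a single causal gene: genomics, epigenomics
and transcriptomics studies each nominate long, largely non-overlapping gene
lists. `ndprio` is for analysts who want to integrate such tiered gene lists
over a protein–protein interaction network: it ranks every gene by how much
evidence it carries and how much evidence its network neighborhood carries,
tests which genes sit unexpectedly close to a curated "core" gene set, extracts
a significantly connected multi-omics gene module, and characterizes the
module's topological clusters by pathway and evidence-type enrichment.

## The method in brief

Evidence enters as a genes × layers matrix $X_0$ (1 = major-tier evidence,
0.5 = minor-tier, 0 = none) and diffuses over the interactome's symmetrically
normalized adjacency $W = D^{-1/2} A D^{-1/2}$:

$$X_{t+1} = \alpha W X_t + (1-\alpha)X_0
  \;\;\xrightarrow{t\to\infty}\;\;
  X_{ss} = (1-\alpha)(I-\alpha W)^{-1}X_0, \qquad \alpha = 0.7 .$$

After column-max normalization, gene $i$'s composite score is
$d_i = (\sum_j x^*_{ij})(\sum_j y^*_{ij})$, where $y^*_{ij}$ averages the
three best-scoring direct neighbors of $i$ in layer $j$. Significance comes
from permuting rows of $X_0$ (add-one empirical p-values). The top of the
$d$-ranking is scanned for the gene-set size whose induced edge count is most
extreme against degree-matched resampled gene sets; that slice is the reported
module, and its largest connected component is partitioned into topological
clusters (five `igraph` method families, best Newman modularity $Q$ wins).
Overlap and enrichment statistics are exact hypergeometric upper tails with
Benjamini–Hochberg correction. See the methods vignette
(`vignettes/network-diffusion-prioritization.Rmd`) for the full account.

## Worked example

The package ships a synthetic-data generator that plants a connected,
densified 50-gene module in a 1000-gene scale-free interactome and sprinkles
three tiered evidence layers over it — the structure the analysis assumes,
with known ground truth:

```r
library(ndprio)

sim   <- generate_synthetic(synthetic_spec(seed = 1))
paths <- write_fixture(sim, "fixtures")
res   <- run_pipeline(default_config(
  edges = paths[["edges"]], gene_lists = paths[["gene_lists"]],
  gmt = paths[["gmt"]], layer_order = c("G", "E", "T"),
  n_perm = 100, seed = 17))
res
#> ndprio pipeline result
#> interactome: 1000 nodes, 6115 edges (score >= 700)
#> gene module: 50 genes (k* = 50), 209 internal edges, largest component 50 genes
#> partition (greedy): 5 clusters over 50 genes, Q = 0.2323
```

The resampling scan shows why 50 genes: the connectivity z-score against
degree-matched null sets peaks exactly at the planted size,

```r
head(res$resampling[, c("k", "omega", "z", "p")], 4)
#>     k omega    z     p
#> 1  25    73 14.6 0.001
#> 2  50   209 17.9 0.001
#> 3  75   392 10.4 0.001
#> 4 100   515  9.8 0.001
```

and the recovered module matches the planted truth (Jaccard 0.96 here):

```r
jaccard <- length(intersect(res$module$genes, sim$truth$planted)) /
           length(union(res$module$genes, sim$truth$planted))
#> 0.961
```

The statistical building blocks are exported on their own. For example, the
probability that a gene with 21 interactors hits 8 members of a 334-gene core
set in a 12,739-gene interactome, and the expected/observed overlap of two
evidence gene lists:

```r
hypergeom_upper_tail(12739, 334, 21, 8)
#> 3.103757e-08

overlap_stats(1133, 1227, 12739, 146)
#> overlap test: |A|=1133 |B|=1227 |U|=12739, observed 146, expected 109, P(X>=obs)=0.000109
```

Real analyses substitute the fixture paths with a STRING-style edge TSV
(`nodeA nodeB score`), a tiered gene-list TSV (`gene layer tier`) and an
optional GMT of pathway gene sets; all inputs must share one gene-identifier
namespace.

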
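# recnet

Receptor prioritization from single-cell RNA-seq by network neighborhood
enrichment and co-expression clustering.

## The problem

Which cell-surface receptors matter for a cell type of interest — for
example, which receptors drive angiogenic signaling in choroidal endothelial
cells (EC)? A receptor's own transcript is often a weak witness: what marks
an *active* receptor is that the genes around it in a functional interaction
network respond. `recnet` implements that idea as a reusable, tested
pipeline:

1. **Differential expression.** Each gene is tested target-type-vs-rest with
   a two-sided Wilcoxon rank-sum test on log-normalized values
   (`log(1 + 10^4 · c / Σc)`), with log2 fold change computed on de-logged
   means plus pseudocount 1 and Benjamini–Hochberg FDR control. A gene is
   called DE when `FDR < α` and `|log2FC| ≥ 0.25`.
2. **Neighborhood enrichment.** For every candidate receptor/TF *g*, its
   direct neighbors in an undirected gene interaction network (the role
   played by composite networks such as the Parsimonious Composite Network)
   are tested for over-representation of DE genes with the upper-tail
   hypergeometric probability

   P(X ≥ k), X ~ Hypergeom(N, K, n),

   where *N* is the universe (genes present in both the expression matrix
   and the network, minus *g*), *K* the DE genes in the universe, *n* the
   in-universe neighborhood size and *k* the DE neighbors. Candidates are
   selected at BH FDR < 0.05 across candidates.
3. **Co-expression clustering.** The selected candidates are correlated
   (Spearman by default) across the target-type cells and clustered by
   hierarchical agglomeration with distance `1 − correlation` and average
   linkage, cut to `k` clusters (`k = 6` by default).
4. **Seed-cluster enrichment.** The cluster containing the seed receptors
   (default the VEGF receptors `KDR`/`FLT1`) is tested for gene-set
   enrichment (e.g. angiogenesis, GO:0001525) with the same hypergeometric
   tail.

The package also provides marker-score cell typing, per-cell-type expression
summaries (fraction of cells expressing, mean log-normalized level — the
numbers behind per-type violin plots), readers/writers for 10x-style
MatrixMarket triplets, dense TSV, GMT, edge lists and label tables, and a
planted-truth negative-binomial simulator so every stage is verifiable
without downloading data.

## Worked example

Simulate a dataset at the default study scale (5 cell types × 400 cells,
2,000 genes, 15 true receptors in 3 co-expression modules plus 45 decoys)
and screen it:

```r
library(recnet)

sim <- simulate_dataset(simulation_params(seed = 42))
fit <- receptor_screen(sim$expr, sim$network, sim$candidates,
                       markers = sim$markers, gene_sets = sim$gene_sets,
                       target_type = "endothelial", k = 3,
                       summary_genes = c("KDR", "FLT1", "RCPT08"))
summary(fit)
```

```
receptor_screen
  DE genes (endothelial vs rest): 160 of 2000
  candidates selected: 15 of 60 (BH fdr < 0.05)
  seed cluster (KDR/FLT1): cluster 1, 5 genes
  seed-cluster enrichment ANGIOGENESIS_SYNTH: overlap 5/5, p = 0.000333

Cluster sizes:
cluster
1 2 3
5 5 5

Seed cluster members:
  FLT1, KDR, RCPT03, RCPT04, RCPT05
...
```

All 15 planted receptors (and no decoys) are selected; the three planted
modules come back as the three clusters; the cluster containing `KDR` and
`FLT1` is exactly the annotated module, and its enrichment p-value,
1/C(15,5) ≈ 3.3 × 10⁻⁴, is the best achievable for a 5-gene set among 15
clustered genes. The per-type summary table (elided) lists, for each gene
and cell type, the fraction of cells with nonzero expression and the mean
log-normalized level.

On real data, point the same machinery at files instead:

```r
fit <- run_pipeline(pipeline_config(
  expression = "counts/",            # 10x triplet, or dense TSV
  expression_fmt = "mtx10x",
  network = "pcn_edges.tsv",
  candidates = "receptors_tfs.tsv",
  markers = "cell_type_markers.tsv", # or labels = "labels.tsv"
  gene_sets = "go_angiogenesis.gmt",
  out_dir = "reports"))
```

which writes `de_table.tsv`, `receptor_enrichment.tsv`,
`correlation_matrix.tsv`, `cluster_assignment.tsv`,
`cluster_enrichment.tsv`, `expression_summary.tsv` and a JSON run manifest.
A thin command-line wrapper with `simulate` and `run` subcommands lives in
`inst/scripts/recnet-cli.R`.

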
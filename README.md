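# trajentropy

Trajectory inference for single-cell RNA-seq that couples the *static*
geometry of cells in expression space with the *dynamic* geometry of their
gene regulatory networks (GRNs), and derives pseudotime from the transfer
entropy of a cell-state transition matrix.

## The problem and the model

Most trajectory-inference tools order cells using only their positions in
expression space — a static snapshot. Two cells can sit close together in
PCA space while their regulatory programs are moving in different
directions. `trajentropy` measures both:

1. **Gene pooling.** Genes are grouped into *supergenes* — pools of the
   `k` most |r|-correlated genes (Pearson, across cells); a supergene's
   expression is its members' mean. The pool size is picked where the
   supergene count `l(k)` plateaus (sliding-window rule: first pair of
   consecutive windows whose mean `l` differs by less than 2).
2. **Per-cell GRNs.** For every cell, a linearized steady-state model
   `x_i = A_i0 + Σ_{j≠i} A_ij x_j` is fitted over the cell's PCA
   neighborhood by least squares, with the conservation condition
   `Σ_j A_ij = 0` enforced softly through a penalty `[λ Σ_j A_ij]²`.
   Row sums of |A| give each gene's in-strength, column sums its
   out-strength; a cell is a point `(I, O)` in this GRN space.
3. **Coupled cell graph.** The Euclidean distance `D^GRN` in GRN space and
   the PCA distance `D^PCA` are combined by the Hadamard product
   `D = D^PCA ∘ D^GRN` (each min–max scaled first), and a KNN graph with
   `K = 0.1 n` is built on `D`.
4. **Entropy pseudotime.** Transition probabilities
   `P_kl ∝ 1 / D^GRN_kl` give each cell a transfer entropy
   `S_k = −Σ_l P_kl log P_kl`. Transitions are kept only along graph edges
   that descend the entropy landscape (`S_k > S_l`), giving the corrected
   matrix `P^G` with `P^G_kl = exp(−P_kl (S_k − S_l))`, row-scaled to
   α = 0.9 so that the accumulated matrix
   `M = Σ_t (P^G)^t = (I − P^G)^{-1}` exists. Rough pseudotime is the
   distance between rows of `M`: `RPT_k = ‖M_root − M_k‖₂`.
5. **Trajectory.** Cells of each cluster (largest connected piece) are
   merged into a supernode — shared neighbors get weight
   `(W_ik + W_jk)/4`, single connections carry over. Cluster pseudotimes
   (normalized to 0–10) enter through the tick function `f(x) = x + 1/x`
   (minimal at a gap of 1), giving the final cluster adjacency
   `W = Ŵ + 0.2 D^PT`. The cluster MST is the lineage backbone; the cell
   graph is pruned to it and its MST, rooted at the designated origin
   cell, yields directed edges and a geodesic final pseudotime in [0, 1].

The package also ships an exact Gillespie simulator of a five-gene
Hill-regulated circuit, a synthetic linear-lineage generator, and the
directed edge-accuracy metric used to score predicted lineages.

## Worked example

```r
library(trajentropy)

dat <- synthetic_linear_lineage(n_cells = 300, n_clusters = 5, seed = 1)
fit <- infer_trajectory(dat$expression, dat$labels, root_cell = "cell001")
fit
#> Trajectory fit over 300 cells, 5 clusters
#>   supergenes: 4 (pool size 5 )
#>   root: cell001 in cluster C1
#>   directed cluster edges:
#>     C1 -> C2
#>     C2 -> C3
#>     C3 -> C4
#>     C4 -> C5

edge_accuracy(fit$cluster_edges, dat$truth_edges)$accuracy
#> [1] 1
cor(fit$pseudotime$pseudotime, dat$true_stage, method = "spearman")
#> [1] 0.9377243

head(tidy(fit), 4)
#> # A tibble: 4 × 8
#>   cell_id cluster entropy   rpt pseudotime reachable  dim1  dim2
#>   <chr>   <chr>     <dbl> <dbl>      <dbl> <lgl>     <dbl> <dbl>
#> 1 cell001 C1         5.44  0        0      TRUE      -1.83 -1.52
#> 2 cell002 C1         5.43  1.35     0.0356 TRUE      -1.86 -1.51
#> 3 cell003 C1         5.56  1.42     0.0447 TRUE      -1.98 -1.29
#> 4 cell004 C1         5.41  1.31     0.0469 TRUE      -1.78 -1.40

autoplot(fit)                         # cluster layout + lineage arrows
autoplot(fit, colour = "pseudotime")  # pseudotime coloring
```

The five directed edges recover the generating chain exactly and the
final pseudotime orders cells along it (Spearman ρ = 0.94). `tidy()`
returns one row per cell; `glance()` a one-row fit summary.

A command-line front-end wrapping the same functions lives at
`inst/scripts/trajentropy.R` (`simulate`, `run`, `evaluate` subcommands):

```sh
cli=$(Rscript -e 'cat(system.file("scripts/trajentropy.R", package = "trajentropy"))')
Rscript $cli simulate --model linear --out sim --cells 300 --clusters 5 --seed 1
Rscript $cli run --expr sim/expression.csv --labels sim/labels.csv \
    --root cell001 --out traj --truth sim/truth_edges.tsv
```

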
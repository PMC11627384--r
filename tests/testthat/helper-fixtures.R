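# Small fixture builders shared across test files. Everything is generated
# in code under fixed seeds; nothing binary is stored.

random_expression <- function(n_cells, n_genes, seed = 1) {
  set.seed(seed)
  vals <- matrix(rexp(n_cells * n_genes, rate = 0.2), n_cells, n_genes)
  expression_matrix(vals,
                    cell_ids = sprintf("c%02d", seq_len(n_cells)),
                    gene_ids = sprintf("g%02d", seq_len(n_genes)))
}

# symmetric, zero-diagonal, positive off-diagonal distance matrix
random_distance <- function(n, seed = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 3), n, 3)
  as.matrix(stats::dist(pts))
}

# nonnegative matrix with rows summing to at most `max_row_sum`
random_substochastic <- function(n, seed = 1, max_row_sum = 0.9) {
  set.seed(seed)
  p <- matrix(runif(n * n), n, n)
  diag(p) <- 0
  target <- runif(n, 0.1, max_row_sum)
  p * target / rowSums(p)
}

# brute-force minimum spanning forest weight by enumerating edge subsets
brute_force_msf_weight <- function(w) {
  n <- nrow(w)
  pairs <- which(upper.tri(w) & !is.na(w), arr.ind = TRUE)
  ne <- nrow(pairs)
  full <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  if (igraph::vcount(full) < n) full <- igraph::add_vertices(full, n - igraph::vcount(full))
  n_comp <- igraph::components(full)$no
  n_need <- n - n_comp
  if (n_need == 0) return(0)
  best <- Inf
  for (sub in utils::combn(ne, n_need, simplify = FALSE)) {
    g <- igraph::graph_from_edgelist(pairs[sub, , drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    comp <- igraph::components(g)
    if (comp$no == n_comp && !igraph::any_loop(g)) {
      # acyclic with n - n_comp edges and n_comp components => spanning forest
      wt <- sum(w[pairs[sub, , drop = FALSE]])
      if (wt < best) best <- wt
    }
  }
  best
}
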
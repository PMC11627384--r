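#' Largest connected component of each cluster
#'
#' Within the cell graph, each cluster's cells may fall into several
#' connected pieces; only the largest piece represents the cluster at the
#' cluster level (ties go to the piece containing the smallest cell index).
#'
#' @param graph KNN graph from [knn_graph()].
#' @param labels Character vector of cluster labels, one per cell (in cell
#'   order).
#' @return Named list mapping cluster label to an integer vector of retained
#'   cell indices.
#' @export
largest_component_per_cluster <- function(graph, labels) {
  n <- nrow(graph$adjacency)
  if (length(labels) != n)
    stop("labels must cover all ", n, " cells", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency != 0,
                                           mode = "undirected")
  out <- list()
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    sub <- igraph::induced_subgraph(g, members)
    comp <- igraph::components(sub)$membership
    sizes <- table(comp)
    best <- as.integer(names(sizes)[sizes == max(sizes)])
    if (length(best) > 1L) {
      # tie: the component holding the smallest original index wins
      firsts <- vapply(best, function(b) min(members[comp == b]), integer(1))
      best <- best[which.min(firsts)]
    }
    out[[cl]] <- members[comp == best]
  }
  out
}

#' Collapse the cell graph to a cluster graph
#'
#' Merges, cluster by cluster, the retained cells of each cluster into one
#' supernode. Members merge pairwise in a fixed order (descending
#' within-cluster degree, ties by cell index — better-connected cells are
#' taken to sit closer to the merged cluster). When both merging nodes
#' connect to an outside node k the new weight is
#' `(W[a,k] + W[b,k]) / 4`; when only one connects, its weight carries over
#' unchanged; edges internal to the merged set vanish.
#'
#' @param graph KNN graph from [knn_graph()].
#' @param labels Cluster label per cell.
#' @param retained Output of [largest_component_per_cluster()]; computed
#'   here when `NULL`.
#' @return List with `weights` (clusters x clusters matrix, `NA` = no
#'   merged edge), `clusters` (label order), and `retained`.
#' @export
merge_clusters <- function(graph, labels, retained = NULL) {
  if (is.null(retained)) retained <- largest_component_per_cluster(graph, labels)
  clusters <- names(retained)
  n <- nrow(graph$adjacency)
  # dense working copy; NA marks "no edge" (a real edge may have tiny weight)
  W <- matrix(NA_real_, n, n)
  e <- graph$edges
  W[cbind(e$from, e$to)] <- e$weight
  W[cbind(e$to, e$from)] <- e$weight
  alive <- rep(TRUE, n)
  rep_of <- integer(length(clusters))           # surviving node per cluster
  keep_cells <- sort(unlist(retained, use.names = FALSE))
  drop_cells <- setdiff(seq_len(n), keep_cells) # outside any largest component
  if (length(drop_cells)) {
    alive[drop_cells] <- FALSE
    W[drop_cells, ] <- NA_real_
    W[, drop_cells] <- NA_real_
  }
  for (ci in seq_along(clusters)) {
    members <- retained[[clusters[ci]]]
    deg <- vapply(members, function(v) {
      sum(!is.na(W[v, members]) & members != v)
    }, numeric(1))
    ord <- members[order(-deg, members)]
    a <- ord[1L]
    for (b in ord[-1L]) {
      outside <- which(alive & seq_len(n) != a & seq_len(n) != b)
      for (k in outside) {
        wa <- W[a, k]; wb <- W[b, k]
        if (!is.na(wa) && !is.na(wb)) {
          w_new <- (wa + wb) / 4
        } else if (!is.na(wb)) {
          w_new <- wb
        } else {
          next                                   # only a connects: unchanged
        }
        W[a, k] <- w_new; W[k, a] <- w_new
      }
      alive[b] <- FALSE
      W[b, ] <- NA_real_; W[, b] <- NA_real_
    }
    W[a, a] <- NA_real_
    rep_of[ci] <- a
  }
  cw <- W[rep_of, rep_of, drop = FALSE]
  dimnames(cw) <- list(clusters, clusters)
  diag(cw) <- NA_real_
  list(weights = cw, clusters = clusters, retained = retained)
}

#' Cluster-level pseudotime
#'
#' Mean rough pseudotime of each cluster's retained cells, min-max
#' normalized across clusters to the range 0-10 (so a difference of 1 is a
#' tenth of the full developmental span).
#'
#' @param rpt Rough pseudotime per cell (from [rough_pseudotime()]).
#' @param retained Output of [largest_component_per_cluster()].
#' @return Named numeric vector of normalized cluster pseudotimes in
#'   `[0, 10]`.
#' @export
cluster_pseudotime <- function(rpt, retained) {
  means <- vapply(retained, function(idx) mean(rpt[idx]), numeric(1))
  rng <- range(means)
  if (rng[2] == rng[1]) {
    warning("all cluster pseudotimes equal; normalized values are all 0")
    return(stats::setNames(rep(0, length(means)), names(means)))
  }
  10 * (means - rng[1]) / (rng[2] - rng[1])
}

#' Tick-function distance between cluster pseudotimes
#'
#' `f(x) = x + 1/x` applied to the absolute pseudotime difference of every
#' cluster pair. f attains its minimum (2) at x = 1: clusters exactly one
#' pseudotime unit apart are the most plausible neighbors along a lineage —
#' neither simultaneous (x near 0, f explodes) nor far apart. Zero
#' differences are floored at `eps` before applying f.
#'
#' @param cluster_pt Named vector from [cluster_pseudotime()].
#' @param eps Floor for zero pseudotime differences (default `1e-6`).
#' @return Symmetric clusters x clusters matrix of tick distances.
#' @export
tick_distance <- function(cluster_pt, eps = 1e-6) {
  if (length(cluster_pt) < 2) stop("need at least 2 clusters", call. = FALSE)
  x <- abs(outer(cluster_pt, cluster_pt, "-"))
  x <- pmax(x, eps)
  d <- x + 1 / x
  diag(d) <- 0
  dimnames(d) <- list(names(cluster_pt), names(cluster_pt))
  d
}

#' Final cluster adjacency combining merged weights and pseudotime
#'
#' `W = What + 0.2 * D_pt`, where `What` is the merged weight matrix
#' max-scaled to `[0, 1]` over existing edges (raw merged weights and tick
#' distances live on unrelated scales). By default only pairs with a merged
#' edge get an entry; `allow_pt_edges = TRUE` additionally connects every
#' pair through the pseudotime term alone.
#'
#' @param merged Result of [merge_clusters()].
#' @param d_pt Tick-distance matrix from [tick_distance()].
#' @param pt_coef Coefficient on the pseudotime distance (default 0.2).
#' @param allow_pt_edges Connect edge-less pairs via pseudotime only.
#' @return Clusters x clusters matrix (`NA` = no edge).
#' @export
cluster_adjacency <- function(merged, d_pt, pt_coef = 0.2,
                              allow_pt_edges = FALSE) {
  wg <- merged$weights
  if (!all(rownames(wg) %in% rownames(d_pt)))
    stop("cluster sets of merged weights and tick distances differ",
         call. = FALSE)
  d_pt <- d_pt[rownames(wg), colnames(wg)]
  mx <- suppressWarnings(max(wg, na.rm = TRUE))
  what <- if (is.finite(mx) && mx > 0) wg / mx else wg
  w <- what + pt_coef * d_pt
  if (allow_pt_edges) {
    fill <- is.na(w) & row(w) != col(w)
    w[fill] <- pt_coef * d_pt[fill]
  }
  diag(w) <- NA_real_
  w
}

#' Minimum spanning forest of the cluster graph
#'
#' One minimum spanning tree per connected component (disconnected lineages
#' stay disconnected). Edges are inserted in lexicographic label order so
#' ties resolve deterministically.
#'
#' @param w Cluster adjacency from [cluster_adjacency()] (`NA` = no edge).
#' @return Tibble of undirected MST edges: `from`, `to`, `weight`.
#' @export
cluster_mst <- function(w) {
  labs <- rownames(w)
  pairs <- which(upper.tri(w) & !is.na(w), arr.ind = TRUE)
  if (nrow(pairs) == 0L)
    return(tibble::tibble(from = character(), to = character(),
                          weight = numeric()))
  ed <- tibble::tibble(from = labs[pairs[, 1]], to = labs[pairs[, 2]],
                       weight = w[pairs])
  ed <- ed[order(ed$from, ed$to), ]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = labs)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  me <- igraph::as_data_frame(mst, what = "edges")
  tibble::tibble(from = pmin(me$from, me$to), to = pmax(me$from, me$to),
                 weight = me$weight)
}

#' Prune the cell graph by the cluster backbone and take the cell MST
#'
#' Keeps every intra-cluster edge (differentiation within a cluster is
#' continuous) and the inter-cluster edges whose cluster pair appears in
#' the cluster MST; all other inter-cluster edges are deleted. The
#' single-cell trajectory is the minimum spanning forest of the pruned
#' graph under the original edge weights.
#'
#' @param graph KNN graph from [knn_graph()].
#' @param cmst Cluster MST tibble from [cluster_mst()].
#' @param labels Cluster label per cell.
#' @return List with `pruned_edges` and `mst_edges` tibbles (`from`, `to`,
#'   `weight`, cell indices).
#' @export
prune_and_cell_mst <- function(graph, cmst, labels) {
  e <- graph$edges
  ca <- labels[e$from]
  cb <- labels[e$to]
  key <- paste(pmin(ca, cb), pmax(ca, cb), sep = "\r")
  allowed <- paste(pmin(cmst$from, cmst$to), pmax(cmst$from, cmst$to),
                   sep = "\r")
  keep <- (ca == cb) | (key %in% allowed)
  pe <- e[keep, , drop = FALSE]
  n <- nrow(graph$adjacency)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(pe$from, pe$to))
  igraph::E(g)$weight <- pe$weight
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  me <- igraph::as_data_frame(mst, what = "edges")
  list(
    pruned_edges = pe,
    mst_edges = tibble::tibble(from = pmin(me$from, me$to),
                               to = pmax(me$from, me$to),
                               weight = me$weight)
  )
}

#' Orient cluster MST edges away from the root
#'
#' Edges in the root's component are directed by tree traversal from the
#' root cluster outwards; components not containing the root fall back to
#' directing each edge from the lower to the higher cluster pseudotime.
#'
#' @param cmst Cluster MST tibble.
#' @param cluster_pt Named cluster pseudotime vector.
#' @param root_cluster Label of the origin cluster.
#' @return Tibble of directed edges: `source`, `target`.
#' @export
orient_edges <- function(cmst, cluster_pt, root_cluster) {
  labs <- names(cluster_pt)
  if (!root_cluster %in% labs)
    stop("root cluster '", root_cluster, "' is not a cluster label",
         call. = FALSE)
  if (nrow(cmst) == 0L)
    return(tibble::tibble(source = character(), target = character()))
  g <- igraph::graph_from_data_frame(cmst[, c("from", "to")],
                                     directed = FALSE, vertices = labs)
  comp <- igraph::components(g)$membership
  src <- character(0); tgt <- character(0)
  root_comp <- comp[[root_cluster]]
  # BFS from the root orients its component
  bfs <- igraph::bfs(g, root = root_cluster, unreachable = FALSE,
                     father = TRUE)
  father <- bfs$father
  for (i in seq_len(nrow(cmst))) {
    a <- cmst$from[i]; b <- cmst$to[i]
    if (comp[[a]] == root_comp) {
      # the BFS father of one endpoint is the other
      if (!is.na(father[[b]]) &&
          igraph::V(g)$name[father[[b]]] == a) {
        src <- c(src, a); tgt <- c(tgt, b)
      } else {
        src <- c(src, b); tgt <- c(tgt, a)
      }
    } else {
      lo <- if (cluster_pt[[a]] <= cluster_pt[[b]]) a else b
      hi <- if (identical(lo, a)) b else a
      src <- c(src, lo); tgt <- c(tgt, hi)
    }
  }
  tibble::tibble(source = src, target = tgt)
}

#' Final pseudotime along the single-cell trajectory
#'
#' Weighted geodesic distance from the root cell along the cell-level
#' minimum spanning forest, min-max scaled to `[0, 1]`. Cells the tree
#' cannot reach from the root get a fallback value from their rough-
#' pseudotime rank (scaled into `[0, 1]`) and are flagged.
#'
#' @param cell_mst MST edge tibble from [prune_and_cell_mst()].
#' @param rpt Rough pseudotime per cell.
#' @param root_cell Index of the root cell.
#' @param n_cells Number of cells.
#' @return Tibble: `cell` (index), `pseudotime` in `[0, 1]`, `reachable`.
#' @export
final_pseudotime <- function(cell_mst, rpt, root_cell, n_cells = length(rpt)) {
  root_cell <- as.integer(root_cell)
  if (is.na(root_cell) || root_cell < 1L || root_cell > n_cells)
    stop("invalid root cell", call. = FALSE)
  g <- igraph::make_empty_graph(n_cells, directed = FALSE)
  if (nrow(cell_mst)) {
    g <- igraph::add_edges(g, rbind(cell_mst$from, cell_mst$to))
    igraph::E(g)$weight <- cell_mst$weight
  }
  geo <- as.numeric(igraph::distances(g, v = root_cell,
                                      weights = igraph::E(g)$weight))
  reach <- is.finite(geo)
  pt <- rep(NA_real_, n_cells)
  if (sum(reach) > 1L) {
    rng <- range(geo[reach])
    pt[reach] <- if (rng[2] > rng[1]) (geo[reach] - rng[1]) / (rng[2] - rng[1])
                 else 0
  } else {
    pt[reach] <- 0
  }
  if (any(!reach)) {
    rk <- rank(rpt, ties.method = "average")
    pt[!reach] <- (rk[!reach] - 1) / max(1, n_cells - 1)
  }
  tibble::tibble(cell = seq_len(n_cells), pseudotime = pt, reachable = reach)
}
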
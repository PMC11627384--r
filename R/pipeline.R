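#' Infer a differentiation trajectory and pseudotime
#'
#' End-to-end pipeline: gene pooling -> per-cell GRN fits -> static (PCA)
#' and dynamic (GRN-space) distances -> Hadamard-coupled KNN graph ->
#' transfer-entropy transition model and rough pseudotime -> cluster-level
#' merge, tick correction and MST -> pruned single-cell MST, directed
#' edges, final pseudotime. Returns a fitted object with [tidy()],
#' [glance()] and [ggplot2::autoplot()] methods.
#'
#' @param em An [expression_matrix()] (cells x genes).
#' @param labels Cluster label per cell: a named character vector (names =
#'   cell ids) or an unnamed vector in cell order.
#' @param root_cell Cell id (or index) of the differentiation origin;
#'   `NULL` picks the cell with maximal transfer entropy (stem-like cells
#'   have the most disordered transitions).
#' @param normalize Normalization method for [normalize_expression()].
#' @param n_components PCA dimensionality (capped at the data rank).
#' @param k_pool Pool size; `NULL` selects it by [select_pool_size()].
#' @param k_grid,window Grid and window for pool-size selection.
#' @param lam Conservation penalty for the GRN fits.
#' @param k_grn GRN neighborhood size (`NULL` = `max(m + 5, 0.1 n)`).
#' @param knn KNN graph neighbor count (`NULL` = `round(0.1 n)`).
#' @param scale_distances Min-max scale the two distance matrices before
#'   the Hadamard product.
#' @param alpha Row sum of the corrected transition matrix (in (0, 1)).
#' @param pt_coef Coefficient on the tick distance in the cluster
#'   adjacency.
#' @param allow_pt_edges Let pseudotime alone create cluster edges.
#' @param seed Seed for the (UMAP) layout; all other stages are
#'   deterministic.
#' @param layout Compute the 2-D layout (`TRUE`/`FALSE`); skipping it saves
#'   time when only edges and pseudotime are needed.
#' @return An object of class `trajentropy_fit`; see Details.
#' @details The returned list carries: `pseudotime` (tibble: cell_id,
#'   cluster, entropy, rpt, pseudotime, reachable), `cluster_edges`
#'   (directed tibble), `cell_mst`, `graph`, `pooling`, `strengths`,
#'   `distances`, `cluster_pt`, `root`, `layout`, and `params`.
#' @export
infer_trajectory <- function(em, labels, root_cell = NULL,
                             normalize = c("none", "libsize_log1p"),
                             n_components = 50,
                             k_pool = NULL, k_grid = 2:50, window = 3,
                             lam = 0.1, k_grn = NULL, knn = NULL,
                             scale_distances = TRUE, alpha = 0.9,
                             pt_coef = 0.2, allow_pt_edges = FALSE,
                             seed = 0, layout = TRUE) {
  normalize <- match.arg(normalize)
  n <- nrow(em)
  ids <- rownames(em)
  labels <- .align_labels(labels, ids)

  em <- normalize_expression(em, normalize)

  # static distance
  ncomp <- min(n_components, n - 1L, ncol(em))
  pca <- pca_distance(em, ncomp)

  # pooling
  cm <- correlation_matrix(em)
  if (is.null(k_pool)) {
    sel <- tryCatch(select_pool_size(em, k_grid, window, cm = cm),
                    error = function(e) NULL)
    k_pool <- if (is.null(sel)) max(2L, min(5L, ncol(em))) else sel$k
  }
  pooling <- supergene_expression(em, pool_genes(cm, k_pool))
  sg <- pooling$supergene_values

  # dynamic distance
  fits <- fit_all_grns(sg, pca$distance, lam = lam, k_grn = k_grn)
  d_grn <- grn_distance(fits$strengths)

  # coupled graph
  d <- combine_distances(pca$distance, d_grn, scale = scale_distances)
  graph <- knn_graph(d, k = knn)

  # transition model
  p_grn <- transition_probabilities(d_grn)
  s <- transfer_entropy(p_grn)
  root_index <- .resolve_root(root_cell, ids, s)
  p_g <- corrected_transitions(p_grn, s, graph, alpha = alpha)
  m <- accumulated_transitions(p_g)
  rpt <- rough_pseudotime(m, root_index)

  # cluster-level trajectory
  retained <- largest_component_per_cluster(graph, labels)
  merged <- merge_clusters(graph, labels, retained)
  cl_pt <- cluster_pseudotime(rpt, retained)
  d_pt <- tick_distance(cl_pt)
  w <- cluster_adjacency(merged, d_pt, pt_coef = pt_coef,
                         allow_pt_edges = allow_pt_edges)
  cmst <- cluster_mst(w)
  root_cluster <- labels[root_index]
  directed <- orient_edges(cmst, cl_pt, root_cluster)

  # cell-level trajectory
  cell <- prune_and_cell_mst(graph, cmst, labels)
  fpt <- final_pseudotime(cell$mst_edges, rpt, root_index, n)

  lay <- NULL
  if (layout) {
    mask <- matrix(0, n, n)
    if (nrow(cell$pruned_edges)) {
      mask[cbind(cell$pruned_edges$from, cell$pruned_edges$to)] <- 1
      mask[cbind(cell$pruned_edges$to, cell$pruned_edges$from)] <- 1
    }
    spec <- tryCatch(spectral_coordinates(p_g * mask),
                     error = function(e) NULL)
    um <- umap_layout(d, seed = seed)
    lay <- if (is.null(spec)) um else combined_embedding(spec, um)
  }

  structure(list(
    pseudotime = tibble::tibble(
      cell_id = ids, cluster = unname(labels), entropy = unname(s),
      rpt = unname(rpt), pseudotime = fpt$pseudotime,
      reachable = fpt$reachable),
    cluster_edges = directed,
    cluster_mst = cmst,
    cell_mst = cell$mst_edges,
    graph = graph,
    pooling = pooling[c("assignment", "k", "l")],
    strengths = fits$strengths,
    distances = list(pca = pca$distance, grn = d_grn, combined = d),
    transition = list(p_grn = p_grn, p_g = p_g, m = m),
    cluster_pt = cl_pt,
    root = list(cell_index = root_index, cell_id = ids[root_index],
                cluster = unname(root_cluster)),
    layout = lay,
    params = list(normalize = normalize, n_components = ncomp,
                  k_pool = pooling$k, l = pooling$l, lam = lam,
                  k_grn = fits$k_grn, knn = graph$k, alpha = alpha,
                  pt_coef = pt_coef, scale_distances = scale_distances,
                  seed = seed)
  ), class = "trajentropy_fit")
}

.align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    missing_ids <- setdiff(ids, names(labels))
    if (length(missing_ids))
      stop("labels missing for cells: ",
           paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
    labels <- labels[ids]
  }
  if (length(labels) != length(ids))
    stop("need one cluster label per cell", call. = FALSE)
  stats::setNames(as.character(labels), ids)
}

.resolve_root <- function(root_cell, ids, s) {
  if (is.null(root_cell)) return(which.max(s))
  if (is.numeric(root_cell)) return(as.integer(root_cell))
  idx <- match(root_cell, ids)
  if (is.na(idx)) stop("root cell '", root_cell, "' not found", call. = FALSE)
  idx
}

#' @export
print.trajentropy_fit <- function(x, ...) {
  cat("Trajectory fit over", nrow(x$pseudotime), "cells,",
      length(x$cluster_pt), "clusters\n")
  cat("  supergenes:", x$params$l, "(pool size", x$params$k_pool, ")\n")
  cat("  root:", x$root$cell_id, "in cluster", x$root$cluster, "\n")
  cat("  directed cluster edges:\n")
  if (nrow(x$cluster_edges))
    cat(paste0("    ", x$cluster_edges$source, " -> ",
               x$cluster_edges$target, collapse = "\n"), "\n")
  else cat("    (none)\n")
  invisible(x)
}
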
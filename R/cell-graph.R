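#' Couple static and dynamic distances
#'
#' Element-wise (Hadamard) product of the PCA-space and GRN-space distance
#' matrices. By default each factor is min-max scaled to `[0, 1]` over its
#' off-diagonal entries first so neither space dominates the product;
#' `scale = FALSE` multiplies the raw matrices.
#'
#' @param d_pca,d_grn Symmetric distance matrices of identical shape.
#' @param scale Min-max scale each factor before multiplying (default TRUE).
#' @return Symmetric combined distance matrix, attribute `kind = "combined"`.
#' @export
combine_distances <- function(d_pca, d_grn, scale = TRUE) {
  if (!all(dim(d_pca) == dim(d_grn)))
    stop("distance matrices have different shapes", call. = FALSE)
  if (scale) {
    d_pca <- .minmax_offdiag(d_pca)
    d_grn <- .minmax_offdiag(d_grn)
  }
  d <- d_pca * d_grn
  attr(d, "kind") <- "combined"
  d
}

.minmax_offdiag <- function(d) {
  off <- d[row(d) != col(d)]
  rng <- range(off)
  if (rng[2] == rng[1]) {
    d[] <- as.numeric(row(d) != col(d))
    return(d)
  }
  out <- (d - rng[1]) / (rng[2] - rng[1])
  diag(out) <- 0
  out
}

#' K-nearest-neighbor cell graph
#'
#' For every cell, undirected edges to its `K` nearest others under `d`
#' (union over cells, so degrees can exceed `K`). `K = max(1, round(0.1 n))`
#' unless given. Ties in distance break by smaller cell index, making the
#' graph deterministic.
#'
#' @param d Combined distance matrix.
#' @param k Neighbor count; `NULL` for the 0.1 n default.
#' @return List with `edges` (tibble: `from`, `to`, `weight`; `from < to`),
#'   `adjacency` (sparse symmetric weight matrix), and `k`.
#' @export
knn_graph <- function(d, k = NULL) {
  n <- nrow(d)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  if (is.null(k)) k <- max(1L, as.integer(round(0.1 * n)))
  k <- min(as.integer(k), n - 1L)
  off <- d[row(d) != col(d)]
  if (length(unique(off)) == 1L)
    warning("all pairwise distances equal; KNN graph decided by index tie-break")
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    nbr <- setdiff(ord, i)[seq_len(k)]
    from <- c(from, rep.int(i, k)); to <- c(to, nbr)
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  w <- pmax(d[cbind(a, b)], 1e-12)  # keep edge weights strictly positive
  adj <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = c(w, w),
                              dims = c(n, n), dimnames = dimnames(d))
  ids <- rownames(d) %||% as.character(seq_len(n))
  list(edges = tibble::tibble(from = a, to = b, weight = w,
                              from_id = ids[a], to_id = ids[b]),
       adjacency = adj, k = k)
}
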
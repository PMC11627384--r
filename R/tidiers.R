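#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory fit
#'
#' One row per cell: identifiers, cluster, transfer entropy, rough and
#' final pseudotime, plus layout coordinates when available.
#'
#' @param x A `trajentropy_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy trajentropy_fit
#' @export
tidy.trajentropy_fit <- function(x, ...) {
  out <- x$pseudotime
  if (!is.null(x$layout))
    out <- dplyr::mutate(out, dim1 = x$layout$coords[, 1],
                         dim2 = x$layout$coords[, 2])
  out
}

#' One-row summary of a trajectory fit
#'
#' @param x A `trajentropy_fit`.
#' @param ... Unused.
#' @return A one-row tibble: cell/cluster counts, pool size, supergene
#'   count, edge count, root id.
#' @method glance trajentropy_fit
#' @export
glance.trajentropy_fit <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$pseudotime),
    n_clusters = length(x$cluster_pt),
    k_pool = x$params$k_pool,
    n_supergenes = x$params$l,
    knn = x$params$knn,
    n_cluster_edges = nrow(x$cluster_edges),
    root_cell = x$root$cell_id,
    root_cluster = x$root$cluster
  )
}
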
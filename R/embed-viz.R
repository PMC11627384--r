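#' Spectral coordinates of the transition structure
#'
#' Eigen-decomposes the row-normalized transition matrix and takes the two
#' eigenvectors whose eigenvalues have the largest magnitude, excluding
#' eigenvalues equal to 1 (the stationary directions carry no layout
#' information). Real parts are used if the spectrum is complex (with a
#' warning beyond a tolerance); each vector's sign is fixed so its
#' largest-magnitude entry is positive, making the output reproducible.
#'
#' @param transition Square nonnegative matrix (e.g. the corrected
#'   transition matrix restricted to the pruned graph); rows with positive
#'   sum are normalized to 1.
#' @param tol Magnitude below which imaginary parts are ignored silently.
#' @return List with `coords` (cells x 2) and `source = "spectral"`.
#' @export
spectral_coordinates <- function(transition, tol = 1e-8) {
  p <- as.matrix(transition)
  rs <- rowSums(p)
  nz <- rs > 0
  p[nz, ] <- p[nz, , drop = FALSE] / rs[nz]
  ev <- eigen(p)
  keep <- which(abs(ev$values - 1) > 1e-8)
  if (length(keep) < 2)
    stop("spectrum is degenerate: fewer than two eigenvalues differ from 1",
         call. = FALSE)
  ord <- keep[order(-abs(ev$values[keep]))][1:2]
  vecs <- ev$vectors[, ord, drop = FALSE]
  if (max(abs(Im(vecs))) > tol)
    warning("complex eigenvectors; using real parts")
  vecs <- Re(vecs)
  for (j in 1:2) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(coords = vecs, source = "spectral")
}

#' UMAP layout of the combined cell-cell distance
#'
#' Runs UMAP on the precomputed combined distance matrix with a fixed seed.
#' If the `uwot` package is unavailable, falls back to classical
#' multidimensional scaling of the same distances (deterministic, and also
#' a 2-D metric layout), with a message.
#'
#' @param d Combined distance matrix.
#' @param seed Integer seed for the UMAP optimizer (default 0).
#' @param n_neighbors UMAP neighborhood size (default 15, capped at n - 1).
#' @return List with `coords` (cells x 2) and `source = "umap"` or
#'   `source = "mds"`.
#' @export
umap_layout <- function(d, seed = 0, n_neighbors = 15) {
  n <- nrow(d)
  if (requireNamespace("uwot", quietly = TRUE)) {
    set.seed(seed)
    co <- uwot::umap(stats::as.dist(d), n_neighbors = min(n_neighbors, n - 1),
                     n_components = 2)
    return(list(coords = unname(co), source = "umap"))
  }
  message("uwot not installed; using classical MDS of the combined distances")
  co <- stats::cmdscale(stats::as.dist(d), k = 2)
  list(coords = unname(co), source = "mds")
}

#' Sum two layouts on a common scale
#'
#' Min-max normalizes each input layout per axis to `[-1, 1]` and sums them
#' element-wise, so the combined picture reflects both the transition
#' spectrum and the manifold layout regardless of their native scales.
#' An axis with zero range maps to all zeros.
#'
#' @param a,b Layout lists (`coords` cells x 2).
#' @return List with `coords` (entries in `[-2, 2]`) and
#'   `source = "combined"`.
#' @export
combined_embedding <- function(a, b) {
  ca <- .norm_axes(a$coords)
  cb <- .norm_axes(b$coords)
  if (!all(dim(ca) == dim(cb)))
    stop("layouts have different shapes", call. = FALSE)
  list(coords = ca + cb, source = "combined")
}

.norm_axes <- function(x) {
  apply(x, 2, function(col) {
    rng <- range(col)
    if (rng[2] == rng[1]) return(rep(0, length(col)))
    2 * (col - rng[1]) / (rng[2] - rng[1]) - 1
  })
}
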
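#' Fit the regulatory network of one cell
#'
#' Fits, for each target supergene i, the linearized steady-state model
#' \deqn{x_i = A_{i0} + \sum_{j \ne i} A_{ij} x_j}
#' by least squares over the cell's local neighborhood, with the
#' conservation condition \eqn{\sum_{j \ne i} A_{ij} = 0} enforced softly
#' through a squared penalty:
#' \deqn{\min \sum_{c} \big[A_{i0} + \sum_{j} A_{ij} x_{cj} - x_{ci}\big]^2
#'       + \big[\lambda \sum_{j} A_{ij}\big]^2.}
#' The penalty is implemented as one pseudo-observation with regressor
#' values `lam` and target 0 appended to the design; `lam = 0` is ordinary
#' least squares and `lam -> Inf` forces each row's coefficient sum to 0.
#' (Folding the penalty into the residual before squaring would be
#' absorbed exactly by the free intercept and leave the coefficients
#' untouched for every `lam`, so it cannot express the conservation
#' condition.)
#' A single expression vector cannot identify an m x m network, so the
#' sample set is the cell plus its nearest neighbors in PCA space (chosen by
#' the caller); singular normal equations fall back to a tiny ridge
#' (`1e-8` on the diagonal) and the fallback is flagged.
#'
#' @param sg Cells x supergenes matrix (from [supergene_expression()]).
#' @param cell_index Row index of the focal cell.
#' @param neighbor_indices Row indices of the local sample set (the focal
#'   cell is included automatically).
#' @param lam Conservation penalty \eqn{\lambda \ge 0}.
#' @return A list with `A` (m x m coefficient matrix, zero diagonal, rows =
#'   targets, columns = regulators), `A0` (length-m intercepts), `cell_id`,
#'   and `ridge_fallback` (logical).
#' @export
fit_cell_grn <- function(sg, cell_index, neighbor_indices, lam = 0.1) {
  stopifnot(lam >= 0)
  if (!length(neighbor_indices)) stop("empty neighborhood", call. = FALSE)
  rows <- sort(unique(c(as.integer(cell_index), as.integer(neighbor_indices))))
  x <- sg[rows, , drop = FALSE]
  m <- ncol(x)
  A <- matrix(0, m, m, dimnames = list(colnames(sg), colnames(sg)))
  A0 <- numeric(m)
  fallback <- FALSE
  for (i in seq_len(m)) {
    z <- cbind(1, x[, -i, drop = FALSE])
    y <- x[, i]
    if (lam > 0 && m > 1) {
      z <- rbind(z, c(0, rep(lam, m - 1L)))
      y <- c(y, 0)
    }
    ztz <- crossprod(z)
    zty <- crossprod(z, y)
    beta <- tryCatch(solve(ztz, zty), error = function(e) NULL)
    if (is.null(beta) || rcond(ztz) < 1e-12) {
      beta <- solve(ztz + diag(1e-8, ncol(z)), zty)
      fallback <- TRUE
    }
    A0[i] <- beta[1L]
    A[i, -i] <- beta[-1L]
  }
  list(A = A, A0 = A0,
       cell_id = rownames(sg)[cell_index] %||% as.character(cell_index),
       ridge_fallback = fallback)
}

#' In- and out-strength of a cell's network
#'
#' With targets in rows and regulators in columns, the in-strength of gene i
#' (how strongly it is regulated) is the row sum of absolute coefficients
#' and the out-strength of gene j (how strongly it regulates others) is the
#' column sum. These two length-m vectors are the cell's coordinates in
#' "GRN space".
#'
#' @param grn Result of [fit_cell_grn()].
#' @return List with nonnegative vectors `I` (in-strength) and `O`
#'   (out-strength), both length m.
#' @export
strength_vectors <- function(grn) {
  absA <- abs(grn$A)
  list(I = rowSums(absA), O = colSums(absA))
}

#' Fit per-cell networks for every cell
#'
#' Neighborhoods are the `k_grn` nearest cells in PCA space (plus the cell
#' itself). The default `k_grn = max(m + 5, round(0.1 n))` keeps each local
#' regression overdetermined (more samples than the m + 1 coefficients per
#' target) while staying local.
#'
#' @param sg Cells x supergenes matrix.
#' @param d_pca Static distance matrix from [pca_distance()].
#' @param lam Conservation penalty passed to [fit_cell_grn()].
#' @param k_grn Neighborhood size; `NULL` for the default above.
#' @return List with `strengths` (cells x 2m matrix, in-strengths then
#'   out-strengths), `grns` (list of per-cell fits), and `k_grn`.
#' @export
fit_all_grns <- function(sg, d_pca, lam = 0.1, k_grn = NULL) {
  n <- nrow(sg)
  m <- ncol(sg)
  if (is.null(k_grn)) k_grn <- max(m + 5L, as.integer(round(0.1 * n)))
  k_grn <- min(k_grn, n - 1L)
  grns <- vector("list", n)
  strengths <- matrix(0, n, 2L * m,
                      dimnames = list(rownames(sg),
                                      c(paste0("I_", colnames(sg)),
                                        paste0("O_", colnames(sg)))))
  for (k in seq_len(n)) {
    nbr <- order(d_pca[k, ], seq_len(n))
    nbr <- setdiff(nbr, k)[seq_len(k_grn)]
    grns[[k]] <- fit_cell_grn(sg, k, nbr, lam = lam)
    s <- strength_vectors(grns[[k]])
    strengths[k, ] <- c(s$I, s$O)
  }
  list(strengths = strengths, grns = grns, k_grn = as.integer(k_grn))
}

#' Dynamic cell-cell distance in GRN space
#'
#' Euclidean distance over the concatenated (in-strength, out-strength)
#' coordinates:
#' \deqn{D^{GRN}_{kl} = \sqrt{\lVert I_k - I_l\rVert^2 +
#'       \lVert O_k - O_l\rVert^2}.}
#'
#' @param strengths Cells x 2m strength matrix from [fit_all_grns()] (or any
#'   matrix whose rows are the concatenated (I, O) vectors).
#' @return Symmetric cells x cells distance matrix, attribute
#'   `kind = "GRN"`.
#' @export
grn_distance <- function(strengths) {
  d <- as.matrix(stats::dist(strengths))
  dimnames(d) <- list(rownames(strengths), rownames(strengths))
  attr(d, "kind") <- "GRN"
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
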
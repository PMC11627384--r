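#' Transition probabilities in GRN space
#'
#' The probability that cell k steps to cell l is proportional to the
#' reciprocal GRN-space distance:
#' \deqn{P^{GRN}_{kl} = (1/D_{kl}) / \sum_{l \ne k} (1/D_{kl}).}
#' Self-transitions are excluded; zero off-diagonal distances are floored at
#' `eps` before inversion so coincident cells get (large but finite) weight.
#'
#' @param d_grn Symmetric distance matrix with zero diagonal.
#' @param eps Floor applied to off-diagonal distances (default `1e-12`).
#' @return Row-stochastic cells x cells matrix with zero diagonal.
#' @export
transition_probabilities <- function(d_grn, eps = 1e-12) {
  n <- nrow(d_grn)
  inv <- 1 / pmax(d_grn, eps)
  diag(inv) <- 0
  rs <- rowSums(inv)
  if (any(!is.finite(rs)) || any(rs == 0))
    stop("degenerate distance matrix: a cell has no finite positive ",
         "distance to any other cell", call. = FALSE)
  p <- inv / rs
  dimnames(p) <- dimnames(d_grn)
  p
}

#' Transfer entropy of each cell
#'
#' Shannon entropy (natural log) of the cell's outgoing transition
#' distribution, \eqn{S_k = -\sum_l P_{kl} \log P_{kl}} with
#' \eqn{0 \log 0 := 0}. High entropy marks cells whose next state is
#' maximally uncertain — stem-like, early cells; low entropy marks committed
#' cells.
#'
#' @param p Row-stochastic transition matrix.
#' @return Nonnegative numeric vector, one entry per cell (nats).
#' @export
transfer_entropy <- function(p) {
  plogp <- p * log(p)
  plogp[p == 0] <- 0
  -rowSums(plogp)
}

#' Entropy-corrected, graph-masked transitions
#'
#' Keeps only transitions that descend the entropy landscape along graph
#' edges:
#' \deqn{P^G_{kl} = e^{-P^{GRN}_{kl}(S_k - S_l)} \text{ if } S_k > S_l
#'       \text{ and } \{k,l\} \in G, \text{ else } 0.}
#' The raw exponential is not substochastic, so each nonzero row is then
#' rescaled to sum to `alpha < 1` (preserving within-row proportions), which
#' bounds the spectral radius and guarantees the accumulated series
#' converges. `alpha = NULL` skips the rescaling (literal mode).
#'
#' @param p Transition matrix from [transition_probabilities()].
#' @param s Entropy vector from [transfer_entropy()].
#' @param graph KNN graph from [knn_graph()] (its `adjacency` support is the
#'   mask), or any symmetric adjacency-like matrix.
#' @param alpha Row sum after rescaling, in (0, 1); default 0.9.
#' @return Nonnegative cells x cells matrix; rows sum to `alpha` or 0.
#' @export
corrected_transitions <- function(p, s, graph, alpha = 0.9) {
  adj <- if (is.list(graph)) graph$adjacency else graph
  mask <- as.matrix(adj != 0)
  n <- nrow(p)
  ds <- outer(s, s, "-")            # ds[k,l] = S_k - S_l
  pg <- exp(-p * ds)
  pg[!(ds > 0) | !mask] <- 0
  diag(pg) <- 0
  if (!is.null(alpha)) {
    stopifnot(alpha > 0, alpha < 1)
    rs <- rowSums(pg)
    nz <- rs > 0
    pg[nz, ] <- pg[nz, , drop = FALSE] * (alpha / rs[nz])
  }
  dimnames(pg) <- dimnames(p)
  pg
}

#' Accumulated (infinite-step) transition matrix
#'
#' \deqn{M = \sum_{t \ge 0} (P^G)^t = (I - P^G)^{-1},} the expected number
#' of visits to each cell over an unbounded entropy-descending walk.
#'
#' @param p_g Substochastic matrix from [corrected_transitions()].
#' @return Matrix `M` of the same shape.
#' @export
accumulated_transitions <- function(p_g) {
  n <- nrow(p_g)
  im <- diag(n) - p_g
  if (rcond(im) < 1e-12) {
    rs <- rowSums(p_g)
    bad <- which(rs >= 1 - 1e-9)
    stop("(I - P^G) is numerically singular; rows with sum >= 1: ",
         paste(utils::head(bad, 10), collapse = ", "),
         " — rescale rows (alpha < 1) first", call. = FALSE)
  }
  m <- solve(im)
  dimnames(m) <- dimnames(p_g)
  m
}

#' Rough pseudotime from accumulated transitions
#'
#' Distance between walk profiles: `RPT_k` is the Euclidean norm of the
#' difference between the root cell's row of `M` and cell k's row. Cells
#' whose reachable futures resemble the root's are early; the root itself
#' is at 0.
#'
#' @param m Accumulated transition matrix.
#' @param root_index Row index of the root cell.
#' @return Nonnegative numeric vector; zero at the root.
#' @export
rough_pseudotime <- function(m, root_index) {
  n <- nrow(m)
  root_index <- as.integer(root_index)
  if (is.na(root_index) || root_index < 1L || root_index > n)
    stop("invalid root index", call. = FALSE)
  sqrt(rowSums((m - matrix(m[root_index, ], n, n, byrow = TRUE))^2))
}
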
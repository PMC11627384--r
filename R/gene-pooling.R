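#' Gene-gene Pearson correlation matrix
#'
#' Pearson correlation of every gene pair across cells. Genes with zero
#' variance would give undefined correlations; they are assigned r = 0
#' against every other gene (and r = 1 with themselves) so they fall into
#' late pools rather than poisoning the grouping with `NA`.
#'
#' @param em An [expression_matrix()] with at least two cells.
#' @return Symmetric genes x genes matrix with entries in `[-1, 1]`.
#' @export
correlation_matrix <- function(em) {
  if (nrow(em) < 2) stop("need at least 2 cells", call. = FALSE)
  x <- unclass(em)
  sds <- apply(x, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(x))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  constant <- which(sds == 0)
  if (length(constant)) {
    cm[constant, ] <- 0
    cm[, constant] <- 0
    diag(cm)[constant] <- 1
  }
  dimnames(cm) <- list(colnames(em), colnames(em))
  cm
}

#' Pool genes into supergenes by correlation
#'
#' Greedy grouping: repeatedly seed a new supergene with the unassigned gene
#' of highest total absolute correlation to the remaining unassigned genes,
#' then add its `k - 1` most-|r|-correlated unassigned partners. Absolute
#' correlation is used so strongly anti-correlated genes (same regulatory
#' module, opposite sign) pool together. Ties break by gene index, making
#' the partition deterministic. The final pool may hold fewer than `k` genes.
#'
#' @param cm Correlation matrix from [correlation_matrix()].
#' @param k Pool size (genes per supergene), >= 1.
#' @return A list with `assignment` (tibble: `gene_id`, `supergene`),
#'   `k`, and `l` (number of supergenes).
#' @export
pool_genes <- function(cm, k) {
  g <- nrow(cm)
  if (g == 0) stop("empty correlation matrix", call. = FALSE)
  stopifnot(k >= 1)
  absr <- abs(cm)
  diag(absr) <- 0
  unassigned <- rep(TRUE, g)
  pool_of <- integer(g)
  pool <- 0L
  while (any(unassigned)) {
    pool <- pool + 1L
    idx <- which(unassigned)
    if (length(idx) == 1L) {
      pool_of[idx] <- pool
      unassigned[idx] <- FALSE
      next
    }
    # seed: highest total |r| to the other unassigned genes; ties -> lowest index
    tot <- rowSums(absr[idx, idx, drop = FALSE])
    seed <- idx[which.max(tot)]
    take <- seed
    if (k > 1L) {
      others <- setdiff(idx, seed)
      ord <- others[order(-absr[seed, others], others)]
      take <- c(seed, utils::head(ord, k - 1L))
    }
    pool_of[take] <- pool
    unassigned[take] <- FALSE
  }
  ids <- rownames(cm)
  if (is.null(ids)) ids <- paste0("gene", seq_len(g))
  list(
    assignment = tibble::tibble(gene_id = ids, supergene = pool_of),
    k = as.integer(k),
    l = pool
  )
}

#' Select the pool size by a sliding-window plateau rule
#'
#' Computes the supergene count `l(k)` along `k_grid`, averages `l` over
#' windows of `window` consecutive grid points, and stops at the first pair
#' of consecutive windows whose mean `l` values differ by less than 2: the
#' later window's mean `k` and mean `l` (rounded) are the chosen operating
#' point. This finds where the `l` versus `k` curve has flattened, i.e.
#' where coarser pooling stops changing the reduced dimension.
#'
#' @param em An [expression_matrix()].
#' @param k_grid Increasing integer vector of candidate pool sizes; trimmed
#'   to at most the gene count.
#' @param window Window length (consecutive grid points) for the moving mean.
#' @param cm Optional precomputed correlation matrix (otherwise computed).
#' @return A list with `k`, `l`, `converged` (FALSE if the plateau criterion
#'   never fired and the last window was used), and `profile` (tibble of
#'   `k` and `l` along the grid).
#' @export
select_pool_size <- function(em, k_grid = 2:50, window = 3, cm = NULL) {
  if (is.null(cm)) cm <- correlation_matrix(em)
  k_grid <- sort(unique(as.integer(k_grid)))   # k > gene count just gives l = 1
  n_windows <- length(k_grid) - window + 1L
  if (n_windows < 2L)
    stop("k_grid must cover at least 2 windows of length ", window,
         call. = FALSE)
  l_of_k <- vapply(k_grid, function(k) pool_genes(cm, k)$l, integer(1))
  kbar <- vapply(seq_len(n_windows),
                 function(i) mean(k_grid[i:(i + window - 1L)]), numeric(1))
  lbar <- vapply(seq_len(n_windows),
                 function(i) mean(l_of_k[i:(i + window - 1L)]), numeric(1))
  converged <- FALSE
  pick <- n_windows
  for (i in seq_len(n_windows - 1L)) {
    if (abs(lbar[i] - lbar[i + 1L]) < 2) {
      pick <- i + 1L
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("pool-size plateau criterion never met; using the last window")
  list(
    k = as.integer(round(kbar[pick])),
    l = as.integer(round(lbar[pick])),
    converged = converged,
    profile = tibble::tibble(k = k_grid, l = l_of_k)
  )
}

#' Supergene expression matrix
#'
#' The expression of a supergene in a cell is the arithmetic mean of its
#' member genes' expression in that cell.
#'
#' @param em An [expression_matrix()].
#' @param pooling Result of [pool_genes()]; its assignment must cover every
#'   gene of `em`.
#' @return The pooling list with a `supergene_values` element added
#'   (cells x l matrix, columns `SG1..SGl`).
#' @export
supergene_expression <- function(em, pooling) {
  asn <- pooling$assignment
  missing_genes <- setdiff(asn$gene_id, colnames(em))
  if (length(missing_genes))
    stop("assignment references unknown genes: ",
         paste(utils::head(missing_genes, 5), collapse = ", "), call. = FALSE)
  uncovered <- setdiff(colnames(em), asn$gene_id)
  if (length(uncovered))
    stop("genes not covered by the pooling: ",
         paste(utils::head(uncovered, 5), collapse = ", "), call. = FALSE)
  l <- pooling$l
  x <- unclass(em)[, asn$gene_id, drop = FALSE]
  sg <- vapply(seq_len(l), function(p) {
    rowMeans(x[, asn$supergene == p, drop = FALSE])
  }, numeric(nrow(x)))
  sg <- matrix(sg, nrow = nrow(x), ncol = l,
               dimnames = list(rownames(em), paste0("SG", seq_len(l))))
  pooling$supergene_values <- sg
  pooling
}
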
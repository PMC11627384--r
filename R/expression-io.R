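#' Create an expression matrix object
#'
#' Light wrapper validating a cells-by-genes numeric matrix with unique cell
#' and gene identifiers. All downstream functions take cells as rows.
#'
#' @param values Numeric matrix, cells in rows, genes in columns. Must be
#'   finite and free of `NA`.
#' @param cell_ids,gene_ids Character vectors of unique identifiers; default
#'   to the dimnames of `values`.
#' @return A numeric matrix of class `expr_matrix` with dimnames set.
#' @export
expression_matrix <- function(values,
                              cell_ids = rownames(values),
                              gene_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length (", length(cell_ids), ") != number of rows (",
         nrow(values), ")", call. = FALSE)
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length (", length(gene_ids), ") != number of columns (",
         ncol(values), ")", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing", call. = FALSE)
  dimnames(values) <- list(cell_ids, gene_ids)
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Read an expression matrix from disk
#'
#' Dense CSV/TSV (first column cell ids, header row gene ids) or a
#' Matrix-Market directory in the 10x style: `matrix.mtx` plus one-column
#' sidecars `genes.tsv` (or `features.tsv`) and `barcodes.tsv`. The 10x
#' on-disk convention is genes-by-cells; `transpose = TRUE` (the mtx default)
#' flips to cells-by-genes.
#'
#' @param path File (csv/tsv) or directory (mtx_dir).
#' @param format One of `"csv"`, `"tsv"`, `"mtx_dir"`; default guessed from
#'   `path`.
#' @param transpose Transpose the values after reading. Defaults to `TRUE`
#'   for `mtx_dir`, `FALSE` otherwise.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path, format = NULL, transpose = NULL) {
  if (is.null(format)) {
    format <- if (dir.exists(path)) "mtx_dir"
              else if (grepl("\\.tsv$", path)) "tsv" else "csv"
  }
  format <- match.arg(format, c("csv", "tsv", "mtx_dir"))
  if (format %in% c("csv", "tsv")) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    delim <- if (format == "csv") "," else "\t"
    tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                             progress = FALSE, show_col_types = FALSE,
                             name_repair = "minimal")
    if (anyDuplicated(names(tab)))
      stop("duplicate gene name in header: ",
           paste(unique(names(tab)[duplicated(names(tab))]), collapse = ", "),
           call. = FALSE)
    ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals))
      stop("non-numeric entries in ", path, call. = FALSE)
    rownames(vals) <- ids
    if (isTRUE(transpose)) vals <- t(vals)
    return(expression_matrix(vals))
  }
  # mtx_dir
  if (!dir.exists(path)) stop("directory not found: ", path, call. = FALSE)
  mtx <- .find_one(path, c("matrix.mtx", "*.mtx"))
  genes <- .find_one(path, c("genes.tsv", "features.tsv", "genes.txt"))
  cells <- .find_one(path, c("barcodes.tsv", "cells.tsv", "barcodes.txt"))
  m <- as.matrix(Matrix::readMM(mtx))
  gene_ids <- readr::read_tsv(genes, col_names = FALSE, col_types = readr::cols(),
                              progress = FALSE, show_col_types = FALSE)[[1]]
  cell_ids <- readr::read_tsv(cells, col_names = FALSE, col_types = readr::cols(),
                              progress = FALSE, show_col_types = FALSE)[[1]]
  if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids))
    stop("sidecar mismatch: matrix is ", nrow(m), "x", ncol(m),
         " but found ", length(gene_ids), " gene ids and ",
         length(cell_ids), " cell ids", call. = FALSE)
  dimnames(m) <- list(gene_ids, cell_ids)
  if (is.null(transpose)) transpose <- TRUE
  if (transpose) m <- t(m)
  expression_matrix(m)
}

.find_one <- function(dir, patterns) {
  for (p in patterns) {
    hit <- Sys.glob(file.path(dir, p))
    if (length(hit) >= 1) return(hit[[1]])
  }
  stop("missing file matching ", paste(patterns, collapse = "/"),
       " in ", dir, call. = FALSE)
}

#' Write an expression matrix
#'
#' Inverse of [load_expression()]; `csv`/`tsv` write the dense table,
#' `mtx_dir` writes `matrix.mtx` + `genes.tsv` + `barcodes.tsv`
#' (genes-by-cells on disk, as in the 10x layout).
#'
#' @param em An [expression_matrix()].
#' @param path Output file (csv/tsv) or directory (mtx_dir).
#' @param format One of `"csv"`, `"tsv"`, `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, format = c("csv", "tsv", "mtx_dir")) {
  format <- match.arg(format)
  if (format %in% c("csv", "tsv")) {
    tab <- tibble::as_tibble(unclass(em), rownames = "cell_id")
    delim <- if (format == "csv") "," else "\t"
    readr::write_delim(tab, path, delim = delim)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(t(unclass(em)), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(colnames(em), file.path(path, "genes.tsv"))
    writeLines(rownames(em), file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Normalize an expression matrix
#'
#' `method = "none"` returns the input untouched (the default, so the model
#' equations act on the values as given). `method = "libsize_log1p"` scales
#' every cell to the median library size and applies `log(1 + x)`.
#'
#' @param em An [expression_matrix()].
#' @param method `"none"` or `"libsize_log1p"`.
#' @return An [expression_matrix()].
#' @export
normalize_expression <- function(em, method = c("none", "libsize_log1p")) {
  method <- match.arg(method)
  if (method == "none") return(em)
  libs <- rowSums(em)
  if (any(libs == 0))
    stop("cells with zero total count cannot be library-size normalized: ",
         paste(utils::head(rownames(em)[libs == 0], 5), collapse = ", "),
         call. = FALSE)
  target <- stats::median(libs)
  out <- log1p(unclass(em) * (target / libs))
  expression_matrix(out, rownames(em), colnames(em))
}

#' PCA embedding and static cell-cell distance
#'
#' Centers the expression matrix, runs PCA, and returns the score matrix
#' together with the Euclidean distance matrix between cells in the
#' PCA-transformed space — the static (expression-space) distance used to
#' build the cell graph.
#'
#' @param em An [expression_matrix()].
#' @param n_components Number of components; capped at `min(cells - 1, genes)`.
#' @return A list with `embedding` (cells x d score matrix) and `distance`
#'   (symmetric cells x cells matrix, attribute `kind = "PCA"`).
#' @export
pca_distance <- function(em, n_components = 50) {
  n <- nrow(em)
  max_d <- min(n - 1L, ncol(em))
  if (n_components > max_d)
    stop("n_components (", n_components, ") exceeds min(cells - 1, genes) = ",
         max_d, call. = FALSE)
  pc <- stats::prcomp(unclass(em), center = TRUE, scale. = FALSE,
                      rank. = n_components)
  emb <- pc$x
  d <- as.matrix(stats::dist(emb))
  dimnames(d) <- list(rownames(em), rownames(em))
  attr(d, "kind") <- "PCA"
  list(embedding = emb, distance = d)
}

#' Read a two-column cell-cluster label table
#'
#' @param path CSV with columns `cell_id`, `cluster` (header optional for
#'   exactly-two-column files).
#' @return A named character vector of cluster labels keyed by cell id.
#' @export
load_labels <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(tab) < 2) stop("label table needs two columns", call. = FALSE)
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}
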
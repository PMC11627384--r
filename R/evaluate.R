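#' Directed edge accuracy against a ground-truth lineage
#'
#' Fraction of ground-truth cluster edges recovered by the prediction:
#' `|predicted intersect truth| / |truth|`. Direction counts by default;
#' `directed = FALSE` compares unordered pairs.
#'
#' @param predicted,truth Data frames (or tibbles) with columns `source`,
#'   `target`; `truth` must be nonempty.
#' @param directed Compare edges as ordered pairs (default TRUE).
#' @return List: `accuracy` in `[0, 1]`, `matched`, `total`.
#' @export
edge_accuracy <- function(predicted, truth, directed = TRUE) {
  if (nrow(truth) == 0) stop("ground-truth edge set is empty", call. = FALSE)
  key <- function(df) {
    s <- as.character(df$source); t <- as.character(df$target)
    if (any(s == t)) stop("self-edges are not allowed", call. = FALSE)
    if (directed) paste(s, t, sep = "\r")
    else paste(pmin(s, t), pmax(s, t), sep = "\r")
  }
  tk <- unique(key(truth))
  pk <- if (nrow(predicted)) unique(key(predicted)) else character(0)
  matched <- sum(tk %in% pk)
  list(accuracy = matched / length(tk), matched = matched,
       total = length(tk))
}
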
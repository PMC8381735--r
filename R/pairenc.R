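# Binary rank-pair encoding: the signature's covariates.
#
# For a gene pair (A, B) in canonical orientation (A before B
# lexicographically) and a sample s, the indicator C is 1 when
# expr(A, s) >= expr(B, s) and 0 when expr(A, s) < expr(B, s) (ties count
# as 1). The comparison is within-sample on the raw FPKM scale, which makes
# C invariant to any positive per-sample rescaling — the property that
# removes the need for cross-platform normalization.

pair_id <- function(a, b) paste(a, b, sep = "|")

#' Encode all gene pairs as a binary indicator matrix
#'
#' Enumerates every unordered pair of genes once, in canonical orientation
#' (lexicographically smaller gene first), and sets the indicator to 1 in a
#' sample when the first gene's expression is greater than or equal to the
#' second's.
#'
#' @param expr `expr_matrix` (or plain matrix) of at least 2 genes.
#' @return object of class `pair_matrix`: list with `pairs` (data frame
#'   `geneA`, `geneB`, `pair`), `C` (integer 0/1 matrix, pairs x samples),
#'   and `prevalence` (per-pair fraction of samples with C = 1).
#' @export
encode_pairs <- function(expr) {
  m <- unclass(expr)
  if (nrow(m) < 2) stop_validation("at least 2 genes are required for pairing")
  if (ncol(m) < 1) stop_validation("at least 1 sample is required")
  genes <- sort(rownames(m))
  m <- m[genes, , drop = FALSE]
  cmb <- utils::combn(length(genes), 2L)
  a <- cmb[1L, ]; b <- cmb[2L, ]
  C <- (m[a, , drop = FALSE] >= m[b, , drop = FALSE]) * 1L
  pairs <- data.frame(geneA = genes[a], geneB = genes[b],
                      pair = pair_id(genes[a], genes[b]),
                      stringsAsFactors = FALSE)
  rownames(C) <- pairs$pair
  new_pair_matrix(pairs, C)
}

new_pair_matrix <- function(pairs, C) {
  storage.mode(C) <- "integer"
  structure(list(pairs = pairs, C = C,
                 prevalence = rowMeans(C)),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair matrix: %d pairs x %d samples; prevalence range [%.3f, %.3f]\n",
              nrow(x$C), ncol(x$C),
              if (nrow(x$C)) min(x$prevalence) else NA,
              if (nrow(x$C)) max(x$prevalence) else NA))
  invisible(x)
}

#' Prevalence validity filter for pair indicators
#'
#' Retains a pair only when its indicator prevalence (fraction of samples
#' with C = 1) lies strictly between `lo` and `hi`. Pairs that are nearly
#' constant across samples carry no rank information and are dropped.
#'
#' @param pm `pair_matrix`.
#' @param lo,hi strict prevalence bounds, defaults 0.2 and 0.8.
#' @return filtered `pair_matrix` with attributes `n_retained`, `n_dropped`.
#' @export
filter_pairs <- function(pm, lo = 0.2, hi = 0.8) {
  if (lo >= hi) stop_validation("prevalence bounds require lo < hi")
  keep <- pm$prevalence > lo & pm$prevalence < hi
  out <- new_pair_matrix(pm$pairs[keep, , drop = FALSE],
                         pm$C[keep, , drop = FALSE])
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# restrict a pair matrix to a sample subset (recomputing prevalence)
subset_pair_samples <- function(pm, samples) {
  missing <- setdiff(samples, colnames(pm$C))
  if (length(missing))
    stop_validation("samples absent from pair matrix: %s",
                    paste(utils::head(missing, 5), collapse = ", "))
  new_pair_matrix(pm$pairs, pm$C[, samples, drop = FALSE])
}

# restrict to a pair subset by pair ID
subset_pairs <- function(pm, ids) {
  miss <- setdiff(ids, pm$pairs$pair)
  if (length(miss))
    stop_validation("pairs absent from pair matrix: %s",
                    paste(utils::head(miss, 5), collapse = ", "))
  keep <- match(ids, pm$pairs$pair)
  new_pair_matrix(pm$pairs[keep, , drop = FALSE], pm$C[keep, , drop = FALSE])
}
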
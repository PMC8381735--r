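# Reading and validation of expression, annotation and clinical inputs.
#
# Expression tables are delimited text (TSV or CSV, autodetected by file
# extension) with gene IDs in the first column and sample IDs in the header.
# Values are FPKM-like: non-negative, within-sample normalized.

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' Read an expression matrix with sample group labels
#'
#' Parses a delimited expression table (first column gene IDs, header row
#' sample IDs) and attaches a tumor/normal group label per sample. Duplicate
#' gene rows are collapsed by their arithmetic mean on the FPKM scale.
#'
#' @param path TSV (default) or CSV file; the extension selects the delimiter.
#' @param group_map named character vector or two-column data frame
#'   (`sample`, `group`) mapping every sample ID in the header to
#'   `"tumor"` or `"normal"`.
#' @return numeric matrix (genes x samples) with attribute `group`, a named
#'   factor over the samples; class `expr_matrix`.
#' @export
read_expression <- function(path, group_map) {
  tab <- read_delim_auto(path)
  gene_ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop_validation("expression matrix contains missing values")
  if (any(vals < 0)) stop_validation("expression matrix contains negative values")
  if (is.data.frame(group_map))
    group_map <- stats::setNames(as.character(group_map[[2L]]),
                                 as.character(group_map[[1L]]))
  samples <- colnames(vals)
  if (anyDuplicated(samples)) stop_validation("duplicate sample IDs in header")
  missing <- setdiff(samples, names(group_map))
  if (length(missing))
    stop_validation("samples missing from group_map: %s",
                    paste(missing, collapse = ", "))
  if (anyDuplicated(gene_ids)) {
    vals <- rowsum(vals, gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
    gene_ids <- rownames(vals)
  }
  rownames(vals) <- gene_ids
  make_expr_matrix(vals, group_map[samples])
}

make_expr_matrix <- function(vals, group) {
  group <- factor(as.character(group), levels = c("tumor", "normal"))
  if (anyNA(group)) stop_validation("group labels must be 'tumor' or 'normal'")
  names(group) <- colnames(vals)
  structure(vals, group = group, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  g <- attr(x, "group")
  cat(sprintf("expression matrix: %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x), ncol(x), sum(g == "tumor"), sum(g == "normal")))
  invisible(x)
}

# subsetting keeps the group attribute aligned with retained samples
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  g <- attr(x, "group")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "group") <- g[colnames(out)]
    class(out) <- c("expr_matrix", "matrix", "array")
  }
  out
}

expr_group <- function(x) attr(x, "group")

#' Read a gene catalog (biotype plus immune-gene flag)
#'
#' @param biotype_path two-column table (`gene_id`, `biotype`) with biotype
#'   in `lncRNA`, `protein_coding`, `other`.
#' @param immune_path one-column file of immune-related gene IDs; the flag
#'   is set only on protein-coding entries.
#' @return data frame with columns `gene_id`, `biotype`, `immune`.
#' @export
read_gene_catalog <- function(biotype_path, immune_path) {
  bt <- read_delim_auto(biotype_path)
  names(bt)[1:2] <- c("gene_id", "biotype")
  imm <- readLines(immune_path)
  imm <- imm[nzchar(imm)]
  if (length(imm) && imm[1L] %in% c("gene_id", "gene")) imm <- imm[-1L]
  bt$immune <- bt$gene_id %in% imm & bt$biotype == "protein_coding"
  bt
}

#' Read a clinical table
#'
#' Expected columns: `sample`, `futime` (days), `fustat` (0/1), `age`,
#' `stage`, `T`, `M`, `N`. No filtering is applied; see
#' [filter_clinical()].
#'
#' @param path TSV/CSV file.
#' @return data frame.
#' @export
read_clinical <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("sample", "futime", "fustat")
  if (!all(need %in% names(tab)))
    stop_validation("clinical table must contain columns: %s",
                    paste(need, collapse = ", "))
  tab
}

#' Filter clinical records
#'
#' Removes records with follow-up time under 31 days (strictly: times of
#' exactly 31 days are retained) and collapses duplicated sample IDs to
#' their first occurrence in file order.
#'
#' @param clinical data frame as returned by [read_clinical()].
#' @param min_futime minimum retained follow-up time, in days.
#' @return filtered data frame with attributes `n_retained` and `n_dropped`.
#' @export
filter_clinical <- function(clinical, min_futime = 31) {
  n0 <- nrow(clinical)
  keep <- !duplicated(clinical$sample)
  out <- clinical[keep, , drop = FALSE]
  out <- out[out$futime >= min_futime, , drop = FALSE]
  if (anyNA(out$futime) || any(out$futime <= 0))
    stop_validation("follow-up times must be positive and non-missing")
  if (!is_binary(out$fustat))
    stop_validation("fustat must be 0/1")
  if (nrow(out) == 0L)
    stop_validation("no clinical records remain after filtering")
  rownames(out) <- NULL
  attr(out, "n_retained") <- nrow(out)
  attr(out, "n_dropped") <- n0 - nrow(out)
  out
}

#' Partition an expression matrix into lncRNA and immune-mRNA submatrices
#'
#' @param expr `expr_matrix`.
#' @param catalog gene catalog from [read_gene_catalog()].
#' @return list with elements `lnc` (all lncRNA genes) and `immune`
#'   (immune-flagged protein-coding genes), both `expr_matrix`. Genes absent
#'   from the catalog are excluded with a warning.
#' @export
partition_genes <- function(expr, catalog) {
  genes <- rownames(expr)
  unknown <- setdiff(genes, catalog$gene_id)
  if (length(unknown))
    warning(sprintf("%d gene(s) absent from catalog, excluded: %s%s",
                    length(unknown), paste(utils::head(unknown, 5), collapse = ", "),
                    if (length(unknown) > 5) ", ..." else ""), call. = FALSE)
  bt <- stats::setNames(catalog$biotype, catalog$gene_id)
  imm <- stats::setNames(catalog$immune, catalog$gene_id)
  lnc_ids <- genes[!is.na(bt[genes]) & bt[genes] == "lncRNA"]
  imm_ids <- genes[!is.na(bt[genes]) & bt[genes] == "protein_coding" & imm[genes]]
  list(lnc = expr[lnc_ids, , drop = FALSE],
       immune = expr[imm_ids, , drop = FALSE])
}
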
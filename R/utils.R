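# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# reverse cumulative sum: out[i] = sum(x[i:n])
revcumsum <- function(x) {
  n <- length(x)
  if (n == 0L) return(x)
  rev(cumsum(rev(x)))
}

revcumsum_mat <- function(m) {
  n <- nrow(m)
  if (n <= 1L) return(m)
  out <- apply(m[n:1L, , drop = FALSE], 2L, cumsum)
  out[n:1L, , drop = FALSE]
}

# Deterministic per-stage seed derived from the master seed and a stage label,
# so stages can be rerun independently with unchanged results.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Run an expression under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_binary <- function(x) all(x %in% c(0, 1))

# Ordinal coding of clinical covariates used for ROC comparison and Cox
# adjustment: stage I-IV -> 1-4, T1-T4 -> 1-4, N0-N2 -> 0-2, M0/M1 -> 0/1.
#' Encode clinical covariates on ordinal scales
#'
#' Converts the categorical staging columns of a clinical table to numeric
#' ordinal codes (stage I--IV to 1--4, T1--T4 to 1--4, N0--N2 to 0--2,
#' M0/M1 to 0/1); age is passed through in years. Used when clinical
#' covariates enter ROC comparisons or Cox models as numeric markers.
#'
#' @param clinical data frame with columns `age`, `stage`, `T`, `M`, `N`.
#' @return data frame of numeric columns (same rows as `clinical`).
#' @export
encode_clinical_ordinal <- function(clinical) {
  code <- function(x, levels) {
    if (is.numeric(x)) return(as.numeric(x))
    m <- match(as.character(x), names(levels))
    unname(levels[m])
  }
  out <- data.frame(row.names = seq_len(nrow(clinical)))
  if ("age" %in% names(clinical)) out$age <- as.numeric(clinical$age)
  if ("stage" %in% names(clinical))
    out$stage <- code(clinical$stage, c(I = 1, II = 2, III = 3, IV = 4))
  if ("T" %in% names(clinical))
    out$T <- code(clinical$T, c(T1 = 1, T2 = 2, T3 = 3, T4 = 4))
  if ("M" %in% names(clinical))
    out$M <- code(clinical$M, c(M0 = 0, M1 = 1))
  if ("N" %in% names(clinical))
    out$N <- code(clinical$N, c(N0 = 0, N1 = 1, N2 = 2))
  out
}
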
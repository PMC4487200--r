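# internal helpers shared across modules

# coerce a data.frame / ExpressionSet-like input to a named numeric matrix
.asExprMatrix <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression input must be a numeric matrix (genes x samples)")
  if (is.null(rownames(m))) stop("expression matrix must have row names")
  if (is.null(colnames(m))) stop("expression matrix must have column names")
  if (anyDuplicated(rownames(m))) stop("row identifiers must be unique")
  if (anyDuplicated(colnames(m))) stop("sample identifiers must be unique")
  m
}

# row variance over observed entries, without matrixStats
.rowVars <- function(m, na.rm = FALSE) {
  n <- if (na.rm) rowSums(!is.na(m)) else ncol(m)
  mu <- rowMeans(m, na.rm = na.rm)
  rowSums((m - mu)^2, na.rm = na.rm) / pmax(n - 1, 1)
}

# two-sided p from a t statistic, clamped into (0, 1]
.tPvalue <- function(t, df) {
  p <- 2 * stats::pt(-abs(t), df = df)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# all permutations of 1:n as an (n! x n) matrix; used for exact Spearman p
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- rest[sub]
  }
  out
}

.stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
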
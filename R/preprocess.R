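#' Preprocessing configuration
#'
#' Bundles the tunable parameters of the expression preprocessing chain.
#'
#' @param maxMissingFrac probes with a missing fraction strictly greater than
#'   this are removed (default 0.2, i.e. the ">20 % missing" rule; a probe at
#'   exactly the threshold is retained).
#' @param knnK number of nearest neighbour probes used to impute each missing
#'   value (default 10).
#' @param collapseRule how multiple probes for one gene are combined:
#'   `"max"` (the probe with the highest mean expression represents the gene),
#'   `"mean"` or `"median"` (per-cell aggregation).
#' @param center whether to median-center each row across arrays.
#' @param centerAfterCollapse if `TRUE`, centering is applied to gene rows
#'   after probe collapse rather than to probe rows before it.
#' @return list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(maxMissingFrac = 0.2, knnK = 10,
                             collapseRule = c("max", "mean", "median"),
                             center = TRUE, centerAfterCollapse = FALSE) {
  .stopIfNot(is.numeric(maxMissingFrac) && length(maxMissingFrac) == 1 &&
             maxMissingFrac >= 0 && maxMissingFrac <= 1,
             "maxMissingFrac must lie in [0, 1]")
  .stopIfNot(is.numeric(knnK) && length(knnK) == 1 && knnK >= 1,
             "knnK must be a positive integer")
  cfg <- list(maxMissingFrac = maxMissingFrac, knnK = as.integer(knnK),
              collapseRule = match.arg(collapseRule),
              center = isTRUE(center),
              centerAfterCollapse = isTRUE(centerAfterCollapse))
  class(cfg) <- "PreprocessConfig"
  cfg
}

#' Remove probes with too many missing values
#'
#' Drops every row whose fraction of missing entries is strictly greater than
#' `maxMissingFrac`; rows at exactly the threshold are retained. Column set
#' and row order are unchanged.
#'
#' @param m numeric matrix, probes x samples, `NA` = missing.
#' @param maxMissingFrac threshold in \[0, 1\] (default 0.2).
#' @return the filtered matrix, with attribute `nRemoved`.
#' @export
filterProbesByMissingness <- function(m, maxMissingFrac = 0.2) {
  if (NROW(m) == 0L) stop("no probes")
  m <- .asExprMatrix(m)
  .stopIfNot(is.numeric(maxMissingFrac) && length(maxMissingFrac) == 1 &&
             maxMissingFrac >= 0 && maxMissingFrac <= 1,
             "missingness threshold must lie in [0, 1]")
  frac <- rowMeans(is.na(m))
  keep <- frac <= maxMissingFrac + 1e-12
  out <- m[keep, , drop = FALSE]
  attr(out, "nRemoved") <- sum(!keep)
  out
}

#' Impute missing values by k-nearest-neighbour averaging
#'
#' For each missing cell, the k nearest rows (Euclidean distance per shared
#' observed column; rows missing the target column are not eligible
#' neighbours) are averaged without weighting. Observed cells are returned
#' unchanged. If fewer than `k` eligible neighbours exist, all of them are
#' used.
#'
#' @param m numeric matrix with `NA` for missing entries; every row must have
#'   at least one observed value.
#' @param k number of neighbours (default 10).
#' @return matrix with no missing entries.
#' @export
imputeMissingKnn <- function(m, k = 10) {
  m <- .asExprMatrix(m)
  .stopIfNot(is.numeric(k) && length(k) == 1 && k >= 1,
             "k must be a positive integer")
  k <- as.integer(k)
  if (!anyNA(m)) return(m)
  if (any(rowSums(!is.na(m)) == 0L))
    stop("every row must have at least one observed value")
  if (any(colSums(!is.na(m)) == 0L)) stop("column unimputable")
  out <- m
  targets <- which(rowSums(is.na(m)) > 0L)
  obs <- !is.na(m)
  for (i in targets) {
    diffs <- sweep(m, 2L, m[i, ], "-")
    shared <- rowSums(obs & rep(obs[i, ], each = nrow(m)))
    d2 <- rowSums(diffs^2, na.rm = TRUE) / shared   # mean squared difference
    d2[shared == 0L] <- Inf
    d2[i] <- Inf
    for (j in which(is.na(m[i, ]))) {
      cand <- which(obs[, j] & is.finite(d2))
      if (length(cand) == 0L) stop("column unimputable")
      nb <- cand[order(d2[cand], cand)][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(m[nb, j])
    }
  }
  out
}

#' Median-center each row across arrays
#'
#' Subtracts the per-row median (over observed entries) so that every row's
#' median becomes zero. Idempotent and invariant to per-row constant shifts.
#'
#' @param m numeric matrix.
#' @return centered matrix of identical shape.
#' @export
medianCenterRows <- function(m) {
  m <- .asExprMatrix(m)
  if (nrow(m) == 0L) stop("empty matrix")
  med <- apply(m, 1L, stats::median, na.rm = TRUE)
  m - med
}

#' Collapse probe rows to gene-symbol rows
#'
#' Probes without a gene symbol are dropped. With `rule = "max"` each gene is
#' represented by the single probe with the highest mean expression across
#' samples (ties broken by input order); with `"mean"`/`"median"` the probes
#' are aggregated per cell.
#'
#' @param m numeric matrix, probes x samples.
#' @param annotation data.frame `probe_id`, `gene_symbol` as from
#'   [readProbeAnnotation()]; `NA` symbol = unmapped.
#' @param rule collapse rule.
#' @return gene x sample matrix with attribute `collapseReport` (list with
#'   `nProbesIn`, `nProbesMapped`, `nGenesOut`).
#' @export
collapseProbesToGenes <- function(m, annotation,
                                  rule = c("max", "mean", "median")) {
  m <- .asExprMatrix(m)
  rule <- match.arg(rule)
  sym <- annotation$gene_symbol[match(rownames(m), annotation$probe_id)]
  mapped <- !is.na(sym) & nzchar(sym)
  if (!any(mapped)) stop("annotation covers none of the probes")
  mm <- m[mapped, , drop = FALSE]
  sym <- sym[mapped]
  genes <- unique(sym)
  if (rule == "max") {
    means <- rowMeans(mm, na.rm = TRUE)
    pick <- vapply(genes, function(g) {
      idx <- which(sym == g)
      idx[which.max(means[idx])]
    }, integer(1))
    out <- mm[pick, , drop = FALSE]
  } else {
    fun <- if (rule == "mean") colMeans else
      function(x, ...) apply(x, 2L, stats::median, ...)
    out <- t(vapply(genes, function(g)
      fun(mm[sym == g, , drop = FALSE], na.rm = TRUE),
      numeric(ncol(mm))))
    if (ncol(mm) == 1L) out <- matrix(out, ncol = 1L)  # vapply edge case
  }
  rownames(out) <- genes
  colnames(out) <- colnames(m)
  attr(out, "collapseReport") <- list(nProbesIn = nrow(m),
                                      nProbesMapped = sum(mapped),
                                      nGenesOut = length(genes))
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in order: missingness filtering, k-nearest-neighbour imputation,
#' probe-level median centering (unless `centerAfterCollapse`), probe-to-gene
#' collapse (when an annotation is supplied), and gene-level centering if
#' requested. Stage-by-stage row counts are collected into a run report.
#'
#' @param m numeric matrix, probes x samples.
#' @param annotation optional probe annotation data.frame; when `NULL` the
#'   collapse stage is skipped.
#' @param config a [preprocessConfig()].
#' @return list with `matrix` (the processed matrix) and `report` (named list
#'   of stage counts and the parameters used, serializable as JSON).
#' @export
preprocessExpression <- function(m, annotation = NULL,
                                 config = preprocessConfig()) {
  stopifnot(inherits(config, "PreprocessConfig"))
  m <- .asExprMatrix(m)
  report <- list(parameters = unclass(config),
                 nProbesIn = nrow(m), nSamples = ncol(m))
  m <- filterProbesByMissingness(m, config$maxMissingFrac)
  report$nProbesAfterFilter <- nrow(m)
  if (nrow(m) == 0L) stop("no probes pass the missingness filter")
  m <- imputeMissingKnn(m, config$knnK)
  if (config$center && !config$centerAfterCollapse) m <- medianCenterRows(m)
  if (!is.null(annotation)) {
    m <- collapseProbesToGenes(m, annotation, config$collapseRule)
    report$collapse <- attr(m, "collapseReport")
    attr(m, "collapseReport") <- NULL
  }
  if (config$center && config$centerAfterCollapse) m <- medianCenterRows(m)
  report$nRowsOut <- nrow(m)
  report$centering <- if (!config$center) "none" else
    if (config$centerAfterCollapse) "gene-level" else "probe-level"
  list(matrix = m, report = report)
}
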
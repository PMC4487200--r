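#' Build per-subset centroids from a labelled reference cohort
#'
#' For every intrinsic subset present in the reference labels (minus the
#' excluded ones), the centroid is the arithmetic mean expression of each
#' intrinsic gene over the reference samples carrying that label. Intrinsic
#' genes absent from the reference matrix are dropped and counted.
#'
#' @param ref a [ReferenceCohort-class], or a genes x samples matrix (then
#'   `labels` is required).
#' @param genes intrinsic gene list to build centroids over; defaults to all
#'   reference genes.
#' @param exclude subset labels to leave out (default `"limited"`, the subset
#'   not represented in a diffuse-cutaneous trial population).
#' @param labels named character vector sample -> subset, when `ref` is a bare
#'   matrix.
#' @return a [SubsetCentroids-class].
#' @export
buildSubsetCentroids <- function(ref, genes = NULL, exclude = "limited",
                                 labels = NULL) {
  if (is(ref, "ReferenceCohort")) {
    labels <- subsetLabels(ref)
    expr <- expressionMatrix(ref)
  } else {
    expr <- .asExprMatrix(ref)
    .stopIfNot(!is.null(labels) && !is.null(names(labels)),
               "labels (named by sample) are required with a bare matrix")
  }
  if (is.null(genes)) genes <- rownames(expr)
  shared <- intersect(genes, rownames(expr))
  if (length(shared) == 0L) stop("no shared intrinsic genes")
  nDropped <- length(genes) - length(shared)
  if (nDropped > 0L)
    message(nDropped, " intrinsic genes absent from the reference; ",
            length(shared), " retained")
  labels <- labels[!labels %in% exclude]
  if (length(labels) == 0L) stop("no reference samples after exclusion")
  subsets <- sort(unique(labels))
  ctr <- vapply(subsets, function(s) {
    ids <- names(labels)[labels == s]
    rowMeans(expr[shared, ids, drop = FALSE])
  }, numeric(length(shared)))
  ctr <- matrix(ctr, nrow = length(shared),
                dimnames = list(shared, subsets))
  if (anyNA(ctr)) stop("reference expression for centroid genes must be complete")
  new("SubsetCentroids", centroids = ctr, nDroppedGenes = as.integer(nDropped))
}

# Spearman rho and two-sided p. Exact permutation enumeration for n <= 9
# with untied data; t-approximation (midranks) otherwise.
.spearmanTest <- function(x, y, exactMax = 9L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 shared genes required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero rank variance")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
  if (n <= exactMax && !ties) {
    perms <- .permutations(n)
    scale <- n * (n^2 - 1) / 6
    rhoNull <- 1 - colSums((t(perms) - rx)^2) / scale
    p <- mean(abs(rhoNull) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- .tPvalue(tstat, n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = max(p, .Machine$double.xmin), n = n, method = method)
}

#' Assign a single sample to an intrinsic subset
#'
#' Computes the Spearman correlation (midrank ties; exact permutation p for
#' n <= 9 untied genes, t-approximation otherwise) between the sample's
#' expression vector and each subset centroid over their shared genes, and
#' calls the subset with the highest rho. If the highest-rho and lowest-p
#' subsets differ (possible only when per-subset gene overlap differs) rho
#' wins and a warning is recorded. Ties in rho are broken by smaller p, then
#' alphabetically, with a warning.
#'
#' @param sample named numeric vector of gene expression.
#' @param centroids a [SubsetCentroids-class].
#' @return list with `call`, `margin`, `rho` (named vector), `p` (named
#'   vector), `n_genes`.
#' @export
assignIntrinsicSubset <- function(sample, centroids) {
  stopifnot(is(centroids, "SubsetCentroids"))
  .stopIfNot(!is.null(names(sample)), "sample vector must be gene-named")
  ctr <- centroidMatrix(centroids)
  subsets <- colnames(ctr)
  res <- lapply(subsets, function(s) {
    shared <- intersect(names(sample), rownames(ctr))
    if (length(shared) < 3L) stop("fewer than 3 shared genes with centroids")
    .spearmanTest(as.numeric(sample[shared]), ctr[shared, s])
  })
  rho <- vapply(res, `[[`, numeric(1), "rho")
  p <- vapply(res, `[[`, numeric(1), "p")
  names(rho) <- names(p) <- subsets
  best <- which(rho >= max(rho) - 1e-12)
  if (length(best) > 1L) {
    warning("tied rho between subsets: ", paste(subsets[best], collapse = ", "),
            "; breaking by smaller p then alphabetically")
    best <- best[order(p[best], subsets[best])]
  }
  call <- subsets[best[1L]]
  nGenes <- vapply(res, `[[`, numeric(1), "n")
  if (length(unique(nGenes)) > 1L && which.min(p) != best[1L] &&
      p[which.min(p)] < p[best[1L]] - 1e-12)
    warning("highest-rho and lowest-p subsets differ (unequal gene overlap);",
            " calling by rho (", call, ")")
  margin <- if (length(subsets) > 1L)
    max(rho) - max(rho[-best[1L]]) else NA_real_
  list(call = call, margin = margin, rho = rho, p = p,
       n_genes = nGenes[best[1L]])
}

#' Assign every sample of a matrix to an intrinsic subset
#'
#' Vectorized wrapper around [assignIntrinsicSubset()].
#'
#' @param m genes x samples matrix.
#' @param centroids a [SubsetCentroids-class].
#' @return a [SubsetCalls-class].
#' @export
assignIntrinsicSubsets <- function(m, centroids) {
  m <- .asExprMatrix(m)
  res <- lapply(colnames(m), function(id)
    assignIntrinsicSubset(m[, id], centroids))
  rho <- do.call(rbind, lapply(res, `[[`, "rho"))
  p <- do.call(rbind, lapply(res, `[[`, "p"))
  rownames(rho) <- rownames(p) <- colnames(m)
  calls <- data.frame(
    sample_id = colnames(m),
    call = vapply(res, `[[`, character(1), "call"),
    margin = vapply(res, `[[`, numeric(1), "margin"),
    n_genes = vapply(res, `[[`, numeric(1), "n_genes"),
    stringsAsFactors = FALSE)
  new("SubsetCalls", rho = rho, p = p, calls = calls)
}

#' Score samples against a gene signature
#'
#' The signature score of a sample is the mean (median-centered) expression
#' over the signature genes present in the matrix — the per-sample "centroid"
#' used for signature trajectory plots.
#'
#' @param m genes x samples matrix (expected already centered by the
#'   preprocessing chain).
#' @param geneSet character vector of signature genes.
#' @param samples sample ids to score (default: all columns).
#' @return data.frame `sample_id`, `score`, `n_genes_used`.
#' @export
scoreSignature <- function(m, geneSet, samples = colnames(m)) {
  m <- .asExprMatrix(m)
  present <- intersect(geneSet, rownames(m))
  if (length(present) == 0L) stop("gene set disjoint from the matrix")
  .stopIfNot(all(samples %in% colnames(m)), "unknown sample id")
  sub <- m[present, samples, drop = FALSE]
  data.frame(sample_id = samples,
             score = colMeans(sub),
             n_genes_used = length(present),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-patient baseline-to-post signature deltas
#'
#' Joins baseline and post signature scores through the patient table of a
#' trial cohort so paired statistics can be run on the change.
#'
#' @param cohort a [TrialCohort-class].
#' @param geneSet character vector of signature genes.
#' @return data.frame `patient_id`, `arm`, `improver` (if known), `baseline`,
#'   `post`, `delta`.
#' @export
signatureDelta <- function(cohort, geneSet) {
  stopifnot(is(cohort, "TrialCohort"))
  pts <- patientTable(cohort)
  pts <- pts[!is.na(pts$baseline_sample) & !is.na(pts$post_sample), ]
  base <- scoreSignature(trialExpression(cohort, "baseline"), geneSet,
                         pts$baseline_sample)
  post <- scoreSignature(trialExpression(cohort, "post"), geneSet,
                         pts$post_sample)
  out <- data.frame(patient_id = pts$patient_id, arm = pts$arm,
                    baseline = base$score, post = post$score,
                    delta = post$score - base$score,
                    stringsAsFactors = FALSE)
  if ("improver" %in% names(pts)) out$improver <- pts$improver
  out
}

#' Hierarchical clustering with correlation distance
#'
#' Agglomerative clustering (average linkage by default) on the distance
#' 1 - r, where r is the centered Pearson or uncentered correlation between
#' items. Items with zero variance get correlation 0 to everything (with a
#' warning). Leaf order is the deterministic order produced by
#' [stats::hclust()] for a fixed input order.
#'
#' @param m genes x samples matrix.
#' @param axis cluster `"columns"` (samples) or `"rows"` (genes).
#' @param distance `"pearson"` (centered) or `"uncentered"`.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with `hclust`, `order` (leaf order), `labels`, and `matrix`
#'   (the input reordered along the clustered axis).
#' @export
hierarchicalCluster <- function(m, axis = c("columns", "rows"),
                                distance = c("pearson", "uncentered"),
                                linkage = "average") {
  m <- .asExprMatrix(m)
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  x <- if (axis == "columns") m else t(m)   # items in columns
  if (ncol(x) < 2L) stop("need at least 2 items to cluster")
  if (distance == "pearson") {
    v <- apply(x, 2L, stats::sd)
    if (any(v == 0)) {
      warning("zero-variance item(s); correlation to them set to 0")
      r <- matrix(0, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
      okc <- v > 0
      if (sum(okc) >= 2L) r[okc, okc] <- stats::cor(x[, okc, drop = FALSE])
      diag(r) <- 1
    } else r <- stats::cor(x)
  } else {
    ss <- sqrt(colSums(x^2))
    if (any(ss == 0)) {
      warning("all-zero item(s); uncentered correlation to them set to 0")
      ss[ss == 0] <- Inf
    }
    r <- crossprod(x) / outer(ss, ss)
    diag(r) <- 1
  }
  h <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  ord <- h$order
  reordered <- if (axis == "columns") m[, ord, drop = FALSE]
    else m[ord, , drop = FALSE]
  list(hclust = h, order = ord, labels = colnames(x)[ord],
       matrix = reordered)
}

#' Export a dendrogram as Newick text
#'
#' @param clustering result of [hierarchicalCluster()] (or an `hclust`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDendrogramNewick <- function(clustering, path) {
  h <- if (inherits(clustering, "hclust")) clustering else clustering$hclust
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Export a clustered matrix in CDT/GTR-compatible form
#'
#' Writes the reordered matrix as a CDT-style tab-delimited table (GID, id,
#' NAME, GWEIGHT, then samples) plus, for row clusterings, a GTR table of the
#' merge tree with node correlations (1 - merge height).
#'
#' @param clustering result of [hierarchicalCluster()] with `axis = "rows"`.
#' @param basePath output path without extension; `.cdt` (and `.gtr`) appended.
#' @return character vector of files written, invisibly.
#' @export
writeCdt <- function(clustering, basePath) {
  m <- clustering$matrix
  h <- clustering$hclust
  n <- nrow(m)
  gid <- paste0("GENE", h$order, "X")  # original row index per reordered row
  cdt <- data.frame(GID = gid, UID = rownames(m), NAME = rownames(m),
                    GWEIGHT = 1, m, check.names = FALSE)
  cdtPath <- paste0(basePath, ".cdt")
  utils::write.table(cdt, cdtPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- cdtPath
  merges <- h$merge
  gtr <- data.frame(
    NODEID = paste0("NODE", seq_len(nrow(merges)), "X"),
    LEFT = ifelse(merges[, 1] < 0, paste0("GENE", -merges[, 1], "X"),
                  paste0("NODE", pmax(merges[, 1], 0), "X")),
    RIGHT = ifelse(merges[, 2] < 0, paste0("GENE", -merges[, 2], "X"),
                   paste0("NODE", pmax(merges[, 2], 0), "X")),
    CORRELATION = 1 - h$height)
  gtrPath <- paste0(basePath, ".gtr")
  utils::write.table(gtr, gtrPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(files, gtrPath))
}
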
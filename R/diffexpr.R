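#' Build a two-class assignment
#'
#' @param classA,classB character vectors of sample ids in each class.
#' @param pairs optional named character vector mapping each class-A sample to
#'   its paired class-B sample (required for paired designs; must be a
#'   bijection).
#' @return list of class `ClassAssignment`.
#' @export
classAssignment <- function(classA, classB, pairs = NULL) {
  .stopIfNot(length(intersect(classA, classB)) == 0L,
             "a sample cannot belong to both classes")
  if (!is.null(pairs)) {
    .stopIfNot(setequal(names(pairs), classA) && setequal(pairs, classB) &&
               !anyDuplicated(pairs),
               "pairing must be a bijection between the classes")
  }
  structure(list(classA = classA, classB = classB, pairs = pairs),
            class = "ClassAssignment")
}

#' Read a class/pairing file
#'
#' CSV with columns `sample_id`, `class` (values `A`/`B` or two arbitrary
#' labels; the first label in file order becomes class A) and optional
#' `pair_id` linking paired samples.
#'
#' @param path file path.
#' @return a [classAssignment()].
#' @export
readClassAssignment <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  .stopIfNot(all(c("sample_id", "class") %in% names(df)),
             "class file needs sample_id and class columns")
  lv <- unique(df$class)
  .stopIfNot(length(lv) == 2L, "exactly two classes required")
  a <- df$sample_id[df$class == lv[1L]]
  b <- df$sample_id[df$class == lv[2L]]
  pairs <- NULL
  if ("pair_id" %in% names(df)) {
    pa <- df[df$class == lv[1L], ]
    pb <- df[df$class == lv[2L], ]
    pairs <- stats::setNames(pb$sample_id[match(pa$pair_id, pb$pair_id)],
                             pa$sample_id)
  }
  classAssignment(a, b, pairs)
}

# vectorized one-sample t on rows of a difference matrix
.pairedRowT <- function(d) {
  n <- ncol(d)
  mu <- rowMeans(d)
  v <- .rowVars(d)
  se <- sqrt(v / n)
  t <- mu / se
  list(t = t, df = n - 1, meanDiff = mu, se = se)
}

#' Two-class marker selection by Student t test
#'
#' Per-gene differential expression between two phenotype classes. Unpaired
#' designs use the pooled-variance two-sample t; paired designs apply a
#' one-sample t to per-pair differences (A minus its paired B sample).
#' Zero-variance genes are flagged `degenerate` (p = 1 when the means agree;
#' p = smallest representable value when a nonzero difference has zero
#' variance), never dropped silently. Benjamini-Hochberg q-values are reported
#' for information; significance is called on the unadjusted p.
#'
#' @param m genes x samples matrix.
#' @param classes a [classAssignment()].
#' @param paired use the paired design (requires `pairs` in `classes`).
#' @param alpha significance threshold on the unadjusted p (default 0.05).
#' @param nPerm if > 0, additionally compute permutation p-values from this
#'   many label permutations (unpaired) or sign flips (paired).
#' @return data.frame sorted by p then decreasing |t|: `gene`, `t`, `df`,
#'   `p`, `q`, `mean_diff`, `direction` (`up_in_A`/`up_in_B`), `significant`,
#'   `flag`, and `p_perm` when requested.
#' @export
twoClassMarkerSelection <- function(m, classes, paired = FALSE, alpha = 0.05,
                                    nPerm = 0) {
  m <- .asExprMatrix(m)
  stopifnot(inherits(classes, "ClassAssignment"))
  a <- classes$classA; b <- classes$classB
  .stopIfNot(all(c(a, b) %in% colnames(m)), "unknown sample id in classes")
  if (paired) {
    .stopIfNot(!is.null(classes$pairs), "paired design requires pairing")
    .stopIfNot(length(a) >= 2L, "need at least 2 pairs")
    d <- m[, names(classes$pairs), drop = FALSE] -
         m[, classes$pairs, drop = FALSE]
    tt <- .pairedRowT(d)
    t <- tt$t; df <- tt$df; meanDiff <- tt$meanDiff
  } else {
    .stopIfNot(length(a) >= 2L && length(b) >= 2L,
               "need at least 2 samples per class")
    ma <- m[, a, drop = FALSE]; mb <- m[, b, drop = FALSE]
    n1 <- length(a); n2 <- length(b)
    mu1 <- rowMeans(ma); mu2 <- rowMeans(mb)
    sp2 <- ((n1 - 1) * .rowVars(ma) + (n2 - 1) * .rowVars(mb)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    meanDiff <- mu1 - mu2
    t <- meanDiff / se
    df <- n1 + n2 - 2
  }
  flag <- rep("", length(t))
  p <- .tPvalue(t, df)
  zeroVar <- !is.finite(t)
  if (any(zeroVar)) {
    flag[zeroVar] <- "degenerate"
    zeroDiff <- zeroVar & abs(meanDiff) < .Machine$double.eps^0.5
    t[zeroDiff] <- 0
    p[zeroDiff] <- 1
    infT <- zeroVar & !zeroDiff
    t[infT] <- sign(meanDiff[infT]) * Inf
    p[infT] <- .Machine$double.xmin
  }
  out <- data.frame(gene = rownames(m), t = t, df = df, p = p,
                    q = stats::p.adjust(p, "BH"),
                    mean_diff = meanDiff,
                    direction = ifelse(meanDiff >= 0, "up_in_A", "up_in_B"),
                    significant = p < alpha,
                    flag = flag, stringsAsFactors = FALSE)
  if (nPerm > 0) out$p_perm <- .markerPermP(m, classes, paired, t, nPerm)
  out[order(out$p, -abs(out$t)), , drop = FALSE]
}

# permutation p-values for the marker t statistics
.markerPermP <- function(m, classes, paired, tObs, nPerm) {
  a <- classes$classA; b <- classes$classB
  exceed <- numeric(nrow(m))
  if (paired) {
    d <- m[, names(classes$pairs), drop = FALSE] -
         m[, classes$pairs, drop = FALSE]
    for (i in seq_len(nPerm)) {
      s <- sample(c(-1, 1), ncol(d), replace = TRUE)
      tp <- .pairedRowT(sweep(d, 2L, s, "*"))$t
      exceed <- exceed + (abs(tp) >= abs(tObs) - 1e-12)
    }
  } else {
    all <- c(a, b)
    for (i in seq_len(nPerm)) {
      perm <- sample(all)
      ca <- classAssignment(perm[seq_along(a)], perm[-seq_along(a)])
      tp <- suppressWarnings(
        twoClassMarkerSelection(m, ca, paired = FALSE))
      tp <- tp$t[match(rownames(m), tp$gene)]
      exceed <- exceed + (abs(tp) >= abs(tObs) - 1e-12)
    }
  }
  (exceed + 1) / (nPerm + 1)
}

#' Compare signature scores between two groups
#'
#' Single Student t test on per-sample signature scores: paired (e.g. baseline
#' vs post within the same patients, in matched order) or unpaired (e.g.
#' baseline abatacept vs baseline placebo).
#'
#' @param scoresA,scoresB numeric vectors of signature scores; for a paired
#'   design, element i of each vector belongs to the same patient.
#' @param paired paired or unpaired (pooled-variance) design.
#' @return list `t`, `df`, `p`, `mean_a`, `mean_b`, `mean_diff`, `flag`.
#' @export
compareSignatureGroups <- function(scoresA, scoresB, paired = FALSE) {
  .stopIfNot(length(scoresA) >= 2L && length(scoresB) >= 2L,
             "need at least 2 scores per group")
  if (paired) {
    .stopIfNot(length(scoresA) == length(scoresB),
               "paired design requires equal-length score vectors")
    d <- scoresA - scoresB
    n <- length(d)
    t <- mean(d) / sqrt(stats::var(d) / n)
    df <- n - 1
    meanDiff <- mean(d)
  } else {
    n1 <- length(scoresA); n2 <- length(scoresB)
    sp2 <- ((n1 - 1) * stats::var(scoresA) + (n2 - 1) * stats::var(scoresB)) /
      (n1 + n2 - 2)
    meanDiff <- mean(scoresA) - mean(scoresB)
    t <- meanDiff / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  flag <- ""
  p <- .tPvalue(t, df)
  if (!is.finite(t)) {
    flag <- "degenerate"
    if (abs(meanDiff) < .Machine$double.eps^0.5) { t <- 0; p <- 1 }
    else { t <- sign(meanDiff) * Inf; p <- .Machine$double.xmin }
  }
  list(t = t, df = df, p = p, mean_a = mean(scoresA), mean_b = mean(scoresB),
       mean_diff = meanDiff, flag = flag)
}
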
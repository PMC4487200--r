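# Ranking metrics for GSEA. Signal-to-noise uses the classic variance floor
# (sd >= 0.2 * |mean|, and >= 0.2 absolute) so low-variance genes cannot
# dominate the ranking.
.rankMetric <- function(m, classes, metric = c("s2n", "t")) {
  metric <- match.arg(metric)
  a <- classes$classA; b <- classes$classB
  ma <- m[, a, drop = FALSE]; mb <- m[, b, drop = FALSE]
  mu1 <- rowMeans(ma); mu2 <- rowMeans(mb)
  s1 <- sqrt(.rowVars(ma)); s2 <- sqrt(.rowVars(mb))
  if (metric == "s2n") {
    fix <- function(s, mu) pmax(s, pmax(0.2 * abs(mu), 0.2))
    (mu1 - mu2) / (fix(s1, mu1) + fix(s2, mu2))
  } else {
    n1 <- ncol(ma); n2 <- ncol(mb)
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    (mu1 - mu2) / sqrt(pmax(sp2, 1e-12) * (1 / n1 + 1 / n2))
  }
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score.
# ranked: metric values sorted decreasing; hits: logical membership vector in
# the same order. Returns ES (signed extremum) and the extremum position.
.gseaES <- function(rankedMetric, hits, weight = 1) {
  N <- length(rankedMetric)
  Nh <- sum(hits)
  if (Nh == 0L) stop("set has no genes in the ranked universe")
  if (Nh == N) stop("set spans the entire universe; miss pool empty")
  w <- abs(rankedMetric)^weight
  hitInc <- ifelse(hits, w, 0)
  total <- sum(hitInc)
  if (total == 0) hitInc[hits] <- 1 / Nh else hitInc <- hitInc / total
  missDec <- ifelse(hits, 0, 1 / (N - Nh))
  running <- cumsum(hitInc - missDec)
  iMax <- which.max(abs(running))
  list(es = running[iMax], position = iMax, running = running)
}

#' Gene Set Enrichment Analysis with gene-set permutation null
#'
#' Ranks genes by a two-class metric (signal-to-noise by default), computes
#' the weighted Kolmogorov-Smirnov running-sum enrichment score per set, and
#' builds the null from random gene sets of matched size (sample permutation
#' is unsound at the class sizes of a small trial; it is available behind
#' `permType = "sample"`). NES is ES divided by the mean |null ES| of the same
#' sign; FDR q follows the standard pooled positive/negative-tail procedure
#' with monotonicity enforced within each sign pool.
#'
#' @param m genes x samples matrix with unique gene symbols.
#' @param classes a [classAssignment()].
#' @param sets named list of gene sets (e.g. from [readGmt()]).
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param weight running-sum weighting exponent (default 1).
#' @param metric ranking metric: `"s2n"` or `"t"`.
#' @param minSize,maxSize set-size filters applied after intersecting with
#'   the ranked universe (defaults 15 and 500).
#' @param permType `"geneset"` (default) or `"sample"`.
#' @param fdrThreshold significance threshold on q (default 0.10).
#' @param seed optional integer seed for the permutation draw.
#' @return data.frame: `set`, `size`, `es`, `nes`, `p`, `q`, `significant`,
#'   `core_enrichment` (comma-separated leading-edge genes). Sets entirely
#'   outside the universe are skipped with a message. Attribute `parameters`
#'   records the configuration.
#' @export
gsea <- function(m, classes, sets, nPerm = 1000, weight = 1,
                 metric = c("s2n", "t"), minSize = 15, maxSize = 500,
                 permType = c("geneset", "sample"), fdrThreshold = 0.10,
                 seed = NULL) {
  m <- .asExprMatrix(m)
  metric <- match.arg(metric)
  permType <- match.arg(permType)
  .stopIfNot(nPerm >= 100, "at least 100 permutations required")
  if (!is.null(seed)) set.seed(seed)
  stat <- .rankMetric(m, classes, metric)
  ord <- order(stat, decreasing = TRUE)
  ranked <- stat[ord]
  universe <- rownames(m)[ord]

  keep <- character(0)
  idxSets <- list()
  for (nm in names(sets)) {
    inU <- intersect(sets[[nm]], universe)
    if (length(inU) == 0L) {
      message("set '", nm, "' has no genes in the universe; skipped")
      next
    }
    if (length(inU) == length(universe))
      stop("set '", nm, "' spans the entire universe; ES undefined")
    if (length(inU) < minSize || length(inU) > maxSize) next
    idxSets[[nm]] <- match(inU, universe)
    keep <- c(keep, nm)
  }
  if (length(keep) == 0L) stop("no gene sets pass the size filters")

  N <- length(universe)
  obs <- lapply(idxSets, function(ix) {
    hits <- logical(N); hits[ix] <- TRUE
    .gseaES(ranked, hits, weight)
  })
  es <- vapply(obs, `[[`, numeric(1), "es")

  sizes <- sort(unique(lengths(idxSets)))
  nullES <- vector("list", length(sizes))
  names(nullES) <- as.character(sizes)
  if (permType == "geneset") {
    for (sz in sizes) {
      nullES[[as.character(sz)]] <- vapply(seq_len(nPerm), function(i) {
        hits <- logical(N); hits[sample.int(N, sz)] <- TRUE
        .gseaES(ranked, hits, weight)$es
      }, numeric(1))
    }
  } else {
    samples <- c(classes$classA, classes$classB)
    nA <- length(classes$classA)
    permES <- matrix(NA_real_, nPerm, length(keep))
    for (i in seq_len(nPerm)) {
      perm <- sample(samples)
      ca <- classAssignment(perm[seq_len(nA)], perm[-seq_len(nA)])
      statP <- .rankMetric(m, ca, metric)
      ordP <- order(statP, decreasing = TRUE)
      rankedP <- statP[ordP]
      uP <- rownames(m)[ordP]
      permES[i, ] <- vapply(seq_along(keep), function(j) {
        hits <- logical(N); hits[match(universe[idxSets[[j]]], uP)] <- TRUE
        .gseaES(rankedP, hits, weight)$es
      }, numeric(1))
    }
    nullBySet <- lapply(seq_along(keep), function(j) permES[, j])
  }

  getNull <- function(j) {
    if (permType == "geneset") nullES[[as.character(length(idxSets[[j]]))]]
    else nullBySet[[j]]
  }

  p <- nes <- numeric(length(keep))
  nesNullAll <- list()
  for (j in seq_along(keep)) {
    nl <- getNull(j)
    same <- if (es[j] >= 0) nl[nl >= 0] else nl[nl < 0]
    p[j] <- if (length(same) == 0L) 1 / nPerm else
      max(sum(abs(same) >= abs(es[j])), 1) / length(same)
    mPos <- mean(nl[nl >= 0]); mNeg <- mean(abs(nl[nl < 0]))
    nes[j] <- if (es[j] >= 0) es[j] / mPos else -abs(es[j]) / mNeg
    nesNullAll[[j]] <- ifelse(nl >= 0, nl / mPos, -abs(nl) / mNeg)
  }
  nullNES <- unlist(nesNullAll)

  q <- vapply(seq_along(keep), function(j) {
    if (nes[j] >= 0) {
      pos <- nullNES[nullNES >= 0]
      num <- if (length(pos)) mean(pos >= nes[j]) else 0
      den <- mean(nes[nes >= 0] >= nes[j])
    } else {
      neg <- nullNES[nullNES < 0]
      num <- if (length(neg)) mean(neg <= nes[j]) else 0
      den <- mean(nes[nes < 0] <= nes[j])
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  # enforce monotone non-increasing q with |NES| within each sign pool
  for (sgn in c(1, -1)) {
    pool <- if (sgn > 0) which(nes >= 0) else which(nes < 0)
    if (length(pool) > 1L) {
      o <- pool[order(-abs(nes[pool]))]
      q[o] <- cummax(q[o])
    }
  }

  core <- vapply(seq_along(keep), function(j) {
    ix <- sort(idxSets[[j]])
    pos <- obs[[j]]$position
    lead <- if (es[j] >= 0) ix[ix <= pos] else ix[ix > pos]
    if (es[j] < 0) lead <- rev(lead)
    paste(universe[lead], collapse = ",")
  }, character(1))

  out <- data.frame(set = keep, size = lengths(idxSets)[keep],
                    es = es, nes = nes, p = pmin(p, 1), q = q,
                    significant = q < fdrThreshold,
                    core_enrichment = core,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$nes)), , drop = FALSE]
  attr(out, "parameters") <- list(nPerm = nPerm, weight = weight,
    metric = metric, permType = permType, minSize = minSize,
    maxSize = maxSize, fdrThreshold = fdrThreshold, seed = seed)
  out
}

#' Single-sample GSEA projection
#'
#' For each sample, genes are ordered by decreasing expression (ties broken
#' by stable input order) and the enrichment score is the integrated
#' difference between the weighted empirical distribution of the set genes
#' (weight = rank^alpha, highest expression = rank N) and the unweighted
#' distribution of the remaining genes. Deterministic; no permutation.
#'
#' @param m genes x samples matrix with unique gene symbols.
#' @param sets named list of gene sets.
#' @param alpha rank weighting exponent (default 0.75).
#' @param normalize divide all scores by the range of the projection
#'   (classic ssGSEA output normalization).
#' @return sets x samples numeric matrix with attribute `alpha`; constant
#'   (all-equal) samples score 0 with a warning.
#' @export
ssgseaProject <- function(m, sets, alpha = 0.75, normalize = FALSE) {
  m <- .asExprMatrix(m)
  .stopIfNot(length(sets) > 0L && !is.null(names(sets)),
             "named gene sets required")
  N <- nrow(m)
  scores <- matrix(NA_real_, length(sets), ncol(m),
                   dimnames = list(names(sets), colnames(m)))
  setIdx <- lapply(sets, function(s) which(rownames(m) %in% s))
  if (any(lengths(setIdx) == 0L))
    stop("gene set(s) disjoint from the matrix: ",
         paste(names(sets)[lengths(setIdx) == 0L], collapse = ", "))
  for (sm in seq_len(ncol(m))) {
    x <- m[, sm]
    if (stats::sd(x) == 0) {
      warning("sample ", colnames(m)[sm], " is constant; scores set to 0")
      scores[, sm] <- 0
      next
    }
    ord <- order(x, decreasing = TRUE)        # stable: ties keep input order
    w <- (N:1)^alpha                          # rank N = highest expression
    for (st in seq_along(setIdx)) {
      inSet <- logical(N); inSet[setIdx[[st]]] <- TRUE
      inOrd <- inSet[ord]
      wHit <- ifelse(inOrd, w, 0)
      ecdfIn <- cumsum(wHit) / sum(wHit)
      ecdfOut <- cumsum(!inOrd) / (N - sum(inOrd))
      scores[st, sm] <- sum(ecdfIn - ecdfOut)
    }
  }
  if (normalize) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "alpha") <- alpha
  scores
}

#' Hypergeometric over-representation test
#'
#' Self-contained functional over-representation: for each gene set, the
#' one-sided hypergeometric tail probability of observing at least the seen
#' overlap between the query and the set within the universe, with
#' Benjamini-Hochberg adjustment across the tested sets.
#'
#' @param query character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param universe character vector of all considered genes.
#' @param sets named list of gene sets (intersected with the universe).
#' @param fdrThreshold significance threshold on q (default 0.05).
#' @return data.frame `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`, `significant`, sorted by p.
#' @export
overrepresentationTest <- function(query, universe, sets,
                                   fdrThreshold = 0.05) {
  query <- unique(query); universe <- unique(universe)
  .stopIfNot(length(query) > 0L, "empty query")
  .stopIfNot(all(query %in% universe), "query must be a subset of the universe")
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(s, query))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  out$significant <- out$q < fdrThreshold
  out[order(out$p), , drop = FALSE]
}
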
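# Shared fixtures, built in code at test time.

# small probes x samples matrix with named dimensions
toyMatrix <- function(values, nrow, rowPrefix = "P", colPrefix = "S") {
  m <- matrix(values, nrow = nrow)
  rownames(m) <- paste0(rowPrefix, seq_len(nrow(m)))
  colnames(m) <- paste0(colPrefix, seq_len(ncol(m)))
  m
}

# deterministic random matrix
randomMatrix <- function(nrow, ncol, seed = 1, sd = 1) {
  set.seed(seed)
  toyMatrix(rnorm(nrow * ncol, sd = sd), nrow)
}

# a tiny labelled reference with clean subset structure (not via the
# generator, so generator and classifier can be tested against each other)
tinyReference <- function(nGenes = 60, nPerSubset = 4, effect = 2,
                          sd = 0.3, seed = 11) {
  set.seed(seed)
  subsets <- c("inflammatory", "fibroproliferative", "normal-like")
  ids <- unlist(lapply(subsets, function(s) paste0(s, "_", seq_len(nPerSubset))))
  m <- toyMatrix(rnorm(nGenes * length(ids), sd = sd), nGenes, rowPrefix = "G")
  colnames(m) <- ids
  labels <- setNames(rep(subsets, each = nPerSubset), ids)
  block <- split(seq_len(nGenes), rep(seq_along(subsets), length.out = nGenes))
  for (i in seq_along(subsets))
    m[block[[i]], labels == subsets[i]] <- m[block[[i]], labels == subsets[i]] + effect
  list(expression = m, labels = labels, blocks = block, subsets = subsets)
}

# exhaustive-enumeration Fisher oracle: probability-mass two-sided rule
fisherOracle <- function(a, b, c, d) {
  K <- a + b; n <- a + c; N <- a + b + c + d
  support <- max(0, n - (N - K)):min(K, n)
  probs <- dhyper(support, K, N - K, n)
  pObs <- dhyper(a, K, N - K, n)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# 2^n sign-assignment Wilcoxon oracle (midranks, zeros already removed)
wilcoxonOracle <- function(diffs) {
  nz <- diffs[diffs != 0]
  n <- length(nz)
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  pLower <- mean(Wnull <= W + 1e-9)
  pUpper <- mean(Wnull >= W - 1e-9)
  min(1, 2 * min(pLower, pUpper))
}

# brute-force GSEA running sum for a toy ranking
gseaOracle <- function(rankedMetric, hits, weight = 1) {
  N <- length(rankedMetric)
  Nh <- sum(hits)
  w <- abs(rankedMetric)^weight
  inc <- ifelse(hits, w / sum(w[hits]), -1 / (N - Nh))
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

# direct weighted-ECDF-difference ssGSEA oracle for one sample
ssgseaOracle <- function(x, setGenes, alpha) {
  N <- length(x)
  ord <- order(x, decreasing = TRUE)
  inSet <- names(x)[ord] %in% setGenes
  w <- (N:1)^alpha
  num <- cumsum(ifelse(inSet, w, 0)) / sum(w[inSet])
  den <- cumsum(!inSet) / (N - sum(inSet))
  sum(num - den)
}
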
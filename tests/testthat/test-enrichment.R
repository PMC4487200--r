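# 10-gene two-class toy with a clearly up-regulated 3-gene set
toyGseaData <- function(seed = 13) {
  set.seed(seed)
  m <- toyMatrix(rnorm(10 * 8, sd = 0.3), 10, rowPrefix = "G")
  m[1:3, 1:4] <- m[1:3, 1:4] + 3
  list(m = m,
       ca = classAssignment(paste0("S", 1:4), paste0("S", 5:8)),
       sets = list(up = paste0("G", 1:3), null = paste0("G", 5:8)))
}

test_that("GSEA enrichment score equals the brute-force running sum", {
  toy <- toyGseaData()
  res <- gsea(toy$m, toy$ca, toy$sets, nPerm = 200, minSize = 2,
              seed = 99)
  # recompute the metric and running sum independently
  a <- toy$m[, paste0("S", 1:4)]; b <- toy$m[, paste0("S", 5:8)]
  s2nFix <- function(s, mu) pmax(s, pmax(0.2 * abs(mu), 0.2))
  metric <- (rowMeans(a) - rowMeans(b)) /
    (s2nFix(apply(a, 1, sd), rowMeans(a)) +
     s2nFix(apply(b, 1, sd), rowMeans(b)))
  ord <- order(metric, decreasing = TRUE)
  ranked <- metric[ord]
  hitsUp <- names(ranked) %in% toy$sets$up
  expect_equal(res$es[res$set == "up"], gseaOracle(ranked, hitsUp, 1))
  # a set comprising the very top genes has a positive ES
  expect_gt(res$es[res$set == "up"], 0)
  # core enrichment is inside set-intersect-universe
  core <- strsplit(res$core_enrichment[res$set == "up"], ",")[[1]]
  expect_true(all(core %in% toy$sets$up))

  # with weight 0, a one-gene set at rank r has a closed-form ES
  oneGene <- list(one = names(ranked)[4])
  res0 <- gsea(toy$m, toy$ca, oneGene, nPerm = 200, weight = 0,
               minSize = 1, seed = 99)
  # running sum rises to 1 at rank 4, minus the 3 misses before it (1/9 each)
  expect_equal(res0$es, 1 - 3 / 9)
})

test_that("GSEA rejects degenerate sets and filters by size", {
  toy <- toyGseaData()
  expect_error(gsea(toy$m, toy$ca, list(all = paste0("G", 1:10)),
                    nPerm = 100, minSize = 1), "entire universe")
  expect_message(gsea(toy$m, toy$ca,
                      c(toy$sets, list(out = c("X1", "X2"))),
                      nPerm = 100, minSize = 2, seed = 1), "skipped")
  res <- gsea(toy$m, toy$ca, toy$sets, nPerm = 100, minSize = 4, seed = 1)
  expect_false("up" %in% res$set)             # 3-gene set filtered out
})

test_that("weight-0 ES is invariant to order-preserving metric transforms", {
  toy <- toyGseaData()
  res1 <- gsea(toy$m, toy$ca, toy$sets, nPerm = 100, weight = 0,
               minSize = 2, seed = 5)
  m2 <- toy$m * 4 + 2          # order-preserving transform of expression
  res2 <- gsea(m2, toy$ca, toy$sets, nPerm = 100, weight = 0,
               minSize = 2, seed = 5)
  expect_equal(res1$es, res2$es[match(res1$set, res2$set)])
})

test_that("GSEA agrees with fgsea on the observed enrichment score", {
  skip_if_not_installed("fgsea")
  toy <- toyGseaData()
  a <- toy$m[, paste0("S", 1:4)]; b <- toy$m[, paste0("S", 5:8)]
  s2nFix <- function(s, mu) pmax(s, pmax(0.2 * abs(mu), 0.2))
  metric <- (rowMeans(a) - rowMeans(b)) /
    (s2nFix(apply(a, 1, sd), rowMeans(a)) +
     s2nFix(apply(b, 1, sd), rowMeans(b)))
  res <- gsea(toy$m, toy$ca, toy$sets, nPerm = 100, minSize = 2, seed = 2)
  esFgsea <- fgsea::calcGseaStat(sort(metric, decreasing = TRUE),
    selectedStats = match(toy$sets$up,
                          names(sort(metric, decreasing = TRUE))),
    gseaParam = 1)
  expect_equal(res$es[res$set == "up"], esFgsea, tolerance = 1e-6)
})

test_that("nominal p estimates stabilise as permutations double", {
  toy <- toyGseaData()
  sets <- list(up = toy$sets$up, null = toy$sets$null,
               mid = paste0("G", c(4, 6, 9)))
  # same seed strategy: the doubled run extends the same permutation stream
  p1 <- gsea(toy$m, toy$ca, sets, nPerm = 1000, minSize = 2, seed = 3)
  p2 <- gsea(toy$m, toy$ca, sets, nPerm = 2000, minSize = 2, seed = 3)
  p2 <- p2[match(p1$set, p2$set), ]
  expect_true(all(abs(p1$p - p2$p) < 0.02 + 1e-9))
  # FDR q is monotone non-increasing with |NES| within each sign pool
  for (sgn in c(1, -1)) {
    pool <- p1[sign(p1$nes) == sgn, ]
    if (nrow(pool) > 1) {
      pool <- pool[order(-abs(pool$nes)), ]
      expect_true(all(diff(pool$q) >= -1e-12))
    }
  }
})

test_that("ssGSEA matches the direct ECDF-difference computation", {
  set.seed(23)
  x <- setNames(rnorm(8), paste0("G", 1:8))
  m <- cbind(S1 = x, S2 = x)
  sets <- list(s = c("G2", "G5", "G7"))
  proj <- ssgseaProject(m, sets, alpha = 0.75)
  expect_equal(proj["s", "S1"], ssgseaOracle(x, sets$s, 0.75))
  # identical samples project identically
  expect_equal(proj[, "S1"], proj[, "S2"])

  # a set occupying the top |S| ranks maximises the score over all
  # placements (enumerated on the 8-gene toy)
  ord <- names(sort(x, decreasing = TRUE))
  placements <- combn(8, 3)
  scores <- apply(placements, 2, function(ix)
    ssgseaOracle(x, ord[ix], 0.75))
  topScore <- ssgseaOracle(x, ord[1:3], 0.75)
  expect_equal(max(scores), topScore)

  # alpha = 0, one-gene set: score from the hand ECDF formula
  oneSet <- list(g = "G3")
  r <- which(ord == "G3")          # position in decreasing order
  # direct formula: sum over positions of 1{i>=r} - (#misses<=i)/7
  hand <- sum((seq_len(8) >= r) - cumsum(seq_len(8) != r) / 7)
  expect_equal(unname(ssgseaProject(m, oneSet, alpha = 0)["g", "S1"]), hand)

  # constant sample: score 0 with a warning
  mConst <- cbind(S1 = setNames(rep(1, 8), paste0("G", 1:8)))
  expect_warning(pc <- ssgseaProject(mConst, sets), "constant")
  expect_equal(unname(pc["s", "S1"]), 0)

  # disjoint set errors
  expect_error(ssgseaProject(m, list(bad = c("X1"))), "disjoint")
})

test_that("over-representation p equals the hypergeometric tail sum", {
  universe <- paste0("G", 1:100)
  sets <- list(path = paste0("G", 1:5))
  query <- paste0("G", c(1:3, 50:56))          # k = 3 of K = 5, n = 10
  res <- overrepresentationTest(query, universe, sets)
  tailSum <- sum(dhyper(3:5, 5, 95, 10))
  expect_equal(res$p, tailSum)
  # disjoint query: tail at overlap 0 -> p = 1
  resDisj <- overrepresentationTest(paste0("G", 90:99), universe, sets)
  expect_equal(resDisj$p, 1)
  # exact-match query in a large universe: p extremely small and monotone
  # decreasing in universe size
  pSmall <- overrepresentationTest(paste0("G", 1:5), universe, sets)$p
  expect_lt(pSmall, 1e-6)
  universe2 <- paste0("G", 1:200)
  pBigger <- overrepresentationTest(paste0("G", 1:5), universe2, sets)$p
  expect_lt(pBigger, pSmall)
  expect_error(overrepresentationTest(character(0), universe, sets),
               "empty query")
  expect_error(overrepresentationTest("NOPE", universe, sets), "subset")
})

test_that("GMT files round-trip", {
  sets <- list(a = c("G1", "G2"), b = c("G3", "G4", "G5"))
  f <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(sets, f)
  expect_equal(readGmt(f), sets)
})
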
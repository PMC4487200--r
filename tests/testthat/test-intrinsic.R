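test_that("centroids are per-subset means over the shared gene list", {
  ref <- tinyReference()
  ctr <- buildSubsetCentroids(ref$expression, labels = ref$labels)
  expect_s4_class(ctr, "SubsetCentroids")
  expect_setequal(subsetLabels(ctr), ref$subsets)
  # two-sample mean check on one gene
  infl <- names(ref$labels)[ref$labels == "inflammatory"]
  expect_equal(centroidMatrix(ctr)["G1", "inflammatory"],
               mean(ref$expression["G1", infl]))
  # a single-sample subset yields that sample's vector
  lab1 <- c(ref$labels, setNames("limited", "lim_1"))
  m1 <- cbind(ref$expression, lim_1 = rnorm(nrow(ref$expression)))
  ctr1 <- buildSubsetCentroids(m1, labels = lab1, exclude = character(0))
  expect_equal(centroidMatrix(ctr1)[, "limited"],
               m1[geneList(ctr1), "lim_1"])
  # excluded subsets are absent
  ctr2 <- buildSubsetCentroids(m1, labels = lab1, exclude = "limited")
  expect_false("limited" %in% subsetLabels(ctr2))
  # genes absent from the reference are dropped and counted
  expect_message(
    ctr3 <- buildSubsetCentroids(ref$expression, labels = ref$labels,
                                 genes = c(rownames(ref$expression), "NOPE")),
    "1 intrinsic genes absent")
  expect_equal(ctr3@nDroppedGenes, 1L)
  expect_error(buildSubsetCentroids(ref$expression, labels = ref$labels,
                                    genes = c("X1", "X2")),
               "no shared intrinsic genes")
})

test_that("intrinsic gene retention matches the cross-platform expectation", {
  # 793 intrinsic genes of which 645 on the study platform -> 81.3 % retained
  ref <- tinyReference(nGenes = 793)
  platformGenes <- rownames(ref$expression)[1:645]
  ctr <- suppressMessages(buildSubsetCentroids(
    ref$expression[platformGenes, ], labels = ref$labels,
    genes = rownames(ref$expression)))
  expect_equal(length(geneList(ctr)), 645)
  expect_equal(ctr@nDroppedGenes, 148L)
  expect_equal(100 * length(geneList(ctr)) / 793, 81.3, tolerance = 0.001)
})

test_that("Spearman assignment calls the matching centroid", {
  ref <- tinyReference()
  ctr <- buildSubsetCentroids(ref$expression, labels = ref$labels)
  cm <- centroidMatrix(ctr)
  # sample identical to a centroid: rho = 1, called
  res <- assignIntrinsicSubset(cm[, "inflammatory"], ctr)
  expect_equal(res$call, "inflammatory")
  expect_equal(unname(res$rho["inflammatory"]), 1)
  # negated centroid: that subset is not called (rho = -1)
  resNeg <- assignIntrinsicSubset(-cm[, "inflammatory"], ctr)
  expect_equal(unname(resNeg$rho["inflammatory"]), -1)
  expect_false(resNeg$call == "inflammatory")
  # constant sample vector is rejected
  const <- setNames(rep(1, nrow(cm)), rownames(cm))
  expect_error(assignIntrinsicSubset(const, ctr), "zero rank variance")
  # reference samples get their own label back when within-subset
  # correlation dominates
  calls <- assignIntrinsicSubsets(ref$expression, ctr)
  expect_s4_class(calls, "SubsetCalls")
  expect_equal(subsetCall(calls)$call, unname(ref$labels))
  expect_true(all(rhoMatrix(calls) >= -1 & rhoMatrix(calls) <= 1))
  expect_true(all(pMatrix(calls) > 0 & pMatrix(calls) <= 1))
})

test_that("Spearman rho matches the rank-difference formula and p the oracle", {
  # 5-gene toy, hand-rankable
  x <- setNames(c(10, 20, 30, 40, 50), paste0("g", 1:5))
  y <- c(3, 1, 4, 2, 5)  # ranks of centroid values
  ctr <- new("SubsetCentroids",
             centroids = matrix(y, 5, 1, dimnames = list(names(x), "s1")))
  res <- assignIntrinsicSubset(x, ctr)
  d <- rank(x) - rank(y)
  rhoFormula <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
  expect_equal(unname(res$rho["s1"]), rhoFormula)
  # exact p: enumeration over all 5! permutations
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
  rhoNull <- apply(perms, 1, function(pr) cor(rank(x), pr))
  expect_equal(unname(res$p["s1"]),
               mean(abs(rhoNull) >= abs(rhoFormula) - 1e-12))
})

test_that("assignment is invariant under strictly monotone transforms", {
  ref <- tinyReference()
  ctr <- buildSubsetCentroids(ref$expression, labels = ref$labels)
  set.seed(5)
  for (i in 1:5) {
    s <- ref$expression[, sample(ncol(ref$expression), 1)]
    r1 <- assignIntrinsicSubset(s, ctr)
    r2 <- assignIntrinsicSubset(exp(2 * s) + 3, ctr)   # strictly monotone
    expect_equal(r1$rho, r2$rho)
    expect_equal(r1$call, r2$call)
  }
})

test_that("signature scores are means over present set genes", {
  m <- toyMatrix(c(1, 2, 6, 0, 0, 0), 3, rowPrefix = "G")
  # one-gene set: the gene's value
  s1 <- scoreSignature(m, "G2")
  expect_equal(s1$score, unname(m["G2", ]))
  # 3-gene set with values (1, 2, 6) -> 3
  expect_equal(scoreSignature(m, c("G1", "G2", "G3"))$score[1], 3)
  # all-zero column scores 0
  expect_equal(scoreSignature(m, c("G1", "G2", "G3"))$score[2], 0)
  # absent genes are ignored; fully disjoint sets error
  expect_equal(scoreSignature(m, c("G1", "NOPE"))$n_genes_used[1], 1)
  expect_error(scoreSignature(m, c("X", "Y")), "disjoint")
})

test_that("hierarchical clustering merges identical samples first and matches
           brute-force agglomeration", {
  set.seed(9)
  m <- randomMatrix(20, 4)
  m <- cbind(m, S5 = m[, "S2"])                 # S5 duplicates S2
  hc <- hierarchicalCluster(m, axis = "columns")
  first <- hc$hclust$merge[1, ]
  expect_setequal(colnames(m)[-first], c("S2", "S5"))
  expect_equal(hc$hclust$height[1], 0, tolerance = 1e-12)

  # 3-item toy: verify the merge order and average-linkage height by hand
  x <- toyMatrix(c(1, 2, 3, 4,
                   1.1, 2.2, 2.9, 4.1,
                   4, 3, 2, 1), 4, rowPrefix = "G")
  r <- cor(x)
  d <- 1 - r
  hc3 <- hierarchicalCluster(x, axis = "columns")
  # closest pair is S1, S2; then S3 joins at the average of its two distances
  expect_equal(sort(hc3$hclust$merge[1, ]), c(-2, -1))
  expect_equal(hc3$hclust$height[2], mean(c(d["S1", "S3"], d["S2", "S3"])))
  # reordered matrix follows the leaf order
  expect_identical(colnames(hc3$matrix), hc3$labels)

  # degenerate input and zero-variance handling
  expect_error(hierarchicalCluster(x[1, , drop = FALSE], axis = "rows"),
               "at least 2 items")
  xz <- x; xz[, 2] <- 5
  expect_warning(hierarchicalCluster(xz, axis = "columns"), "zero-variance")

  # Newick export is readable by ape
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeDendrogramNewick(hc3, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, colnames(x))

  # CDT/GTR export writes both files for row clustering
  rows <- hierarchicalCluster(x, axis = "rows")
  base <- withr::local_tempfile()
  files <- writeCdt(rows, base)
  expect_true(all(file.exists(files)))
})

test_that("signature deltas join baseline and post per patient", {
  cfg <- simulationConfig(seed = 21, nGenes = 400, nHealthy = 0,
                          forceImproverFraction = TRUE)
  co <- generateTrialCohort(cfg)
  sets <- groundTruth(co)$signatureSets
  sd1 <- signatureDelta(co, sets$inflammatory_signature)
  biopsied <- patientTable(co)
  biopsied <- biopsied[!is.na(biopsied$baseline_sample), ]
  expect_equal(sd1$patient_id, biopsied$patient_id)
  expect_equal(sd1$delta, sd1$post - sd1$baseline)
})
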
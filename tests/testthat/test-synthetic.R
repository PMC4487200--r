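test_that("generators are deterministic and validate their configuration", {
  cfg <- simulationConfig(seed = 5, nGenes = 300, nReferencePerSubset = 5)
  r1 <- generateReferenceCohort(cfg)
  r2 <- generateReferenceCohort(cfg)
  expect_identical(expressionMatrix(r1), expressionMatrix(r2))
  c1 <- generateTrialCohort(cfg)
  c2 <- generateTrialCohort(cfg)
  expect_identical(trialExpression(c1, "baseline"),
                   trialExpression(c2, "baseline"))
  expect_identical(visitTable(c1), visitTable(c2))

  expect_error(simulationConfig(), "seed")
  expect_error(simulationConfig(seed = 1, noiseSd = -1), "sds")
  expect_error(simulationConfig(seed = 1, missingnessRate = 2), "fractions")
  expect_error(simulationConfig(seed = 1, nGenes = 100,
                                nSignatureGenes = 50),
               "signature genes exceed")
  expect_error(simulationConfig(seed = 1,
    nBiopsiedPerArm = c(abatacept = 9, placebo = 2)), "biopsy")
})

test_that("reference cohorts carry the configured subset structure", {
  cfg <- simulationConfig(seed = 9, nGenes = 600, nSignatureGenes = 100,
                          nReferencePerSubset = 20)
  ref <- generateReferenceCohort(cfg)
  labels <- subsetLabels(ref)
  expect_equal(as.integer(table(labels)), rep(20L, 3))
  m <- expressionMatrix(ref)
  sets <- groundTruth(ref)$signatureSets
  # background genes: mean within 3 SE of 0
  bg <- setdiff(rownames(m), unlist(sets))
  se <- cfg$noiseSd / sqrt(length(bg) * ncol(m))
  expect_lt(abs(mean(m[bg, ])), 3 * se)
  # signature genes hit their target shift in their own subset
  for (s in c("inflammatory", "fibroproliferative", "normal-like")) {
    own <- m[sets[[paste0(s, "_signature")]], names(labels)[labels == s]]
    seOwn <- cfg$noiseSd / sqrt(length(own))
    expect_lt(abs(mean(own) - cfg$effectSize), 3 * seOwn)
  }
  # a limited subset appears only when configured
  expect_false("limited" %in% labels)
  cfgL <- simulationConfig(seed = 9, nGenes = 600, nSignatureGenes = 100,
                           nReferencePerSubset = 5, includeLimited = TRUE)
  expect_true("limited" %in% subsetLabels(generateReferenceCohort(cfgL)))
})

test_that("zero effect size leaves subsets unrecoverable (null case)", {
  cfg <- simulationConfig(seed = 31, nGenes = 400, effectSize = 0,
                          nReferencePerSubset = 15)
  ref <- generateReferenceCohort(cfg)
  ctr <- buildSubsetCentroids(ref)
  probe <- generateReferenceCohort(
    simulationConfig(seed = 32, nGenes = 400, effectSize = 0,
                     nReferencePerSubset = 15))
  calls <- assignIntrinsicSubsets(expressionMatrix(probe), ctr)
  acc <- mean(subsetCall(calls)$call == subsetLabels(probe))
  expect_lt(acc, 0.6)                      # near chance (~1/3)
})

test_that("trial cohorts respect the clinical design and ground truth", {
  cfg <- simulationConfig(seed = 41, nGenes = 300)
  co <- generateTrialCohort(cfg)
  pts <- patientTable(co)
  expect_equal(sum(pts$arm == "abatacept"), 7)
  expect_equal(sum(pts$arm == "placebo"), 3)
  expect_equal(sum(!is.na(pts$baseline_sample)), 8)
  vis <- visitTable(co)
  expect_equal(nrow(vis), 80)
  expect_true(all(vis$mrss == round(vis$mrss)))
  expect_true(all(vis$mrss >= 0 & vis$mrss <= 51))
  expect_true(all(vis$visit_day %in% defaultVisitSchedule()))
  # improver flags derive from the trajectories by default
  calls <- classifyImprovers(vis)
  expect_equal(unname(groundTruth(co)$improver[calls$patient_id]),
               calls$improver)
  # forced fractions reproduce the 5/7 vs 1/3 split and stay consistent
  cfgF <- simulationConfig(seed = 41, nGenes = 300,
                           forceImproverFraction = TRUE)
  coF <- generateTrialCohort(cfgF)
  impF <- groundTruth(coF)$improver
  arm <- patientTable(coF)$arm
  expect_equal(sum(impF[arm == "abatacept"]), 5)
  expect_equal(sum(impF[arm == "placebo"]), 1)
  callsF <- classifyImprovers(visitTable(coF))
  expect_equal(unname(impF[callsF$patient_id]), callsF$improver)
})

test_that("treated improvers lose their subset signature post-treatment", {
  cfg <- simulationConfig(seed = 55, nGenes = 500,
                          forceImproverFraction = TRUE)
  co <- generateTrialCohort(cfg)
  truth <- groundTruth(co)
  pts <- patientTable(co)
  pts <- pts[!is.na(pts$baseline_sample), ]
  sets <- truth$signatureSets
  deltas <- vapply(seq_len(nrow(pts)), function(i) {
    sig <- sets[[paste0(pts$subset[i], "_signature")]]
    post <- mean(trialExpression(co, "post")[sig, pts$post_sample[i]])
    base <- mean(trialExpression(co, "baseline")[sig, pts$baseline_sample[i]])
    post - base
  }, numeric(1))
  treatedImp <- pts$arm == "abatacept" & pts$improver
  expect_true(all(deltas[treatedImp] < -0.5))          # decay 1.5
  expect_true(all(deltas[!treatedImp] > -0.5))         # drift, not decay
})

test_that("missingness injection keeps matrices imputable", {
  m <- randomMatrix(50, 10)
  mm <- injectMissing(m, 0.2, seed = 3)
  expect_gt(sum(is.na(mm)), 0)
  expect_true(all(rowSums(!is.na(mm)) >= 1))
  expect_true(all(colSums(!is.na(mm)) >= 1))
  expect_identical(mm[!is.na(mm)], m[!is.na(mm)])
  expect_identical(injectMissing(m, 0), m)
})

test_that("cohort files round-trip through the emitted formats", {
  cfg <- simulationConfig(seed = 61, nGenes = 120, nSignatureGenes = 30,
                          nReferencePerSubset = 4, nHealthy = 2)
  dir <- withr::local_tempdir()
  ref <- generateReferenceCohort(cfg)
  rf <- writeReferenceCohort(ref, dir)
  expect_equal(readExpressionMatrix(rf[["expression"]]),
               expressionMatrix(ref))
  expect_equal(readSubsetLabels(rf[["labels"]]), subsetLabels(ref))
  co <- generateTrialCohort(cfg)
  tf <- writeTrialCohort(co, dir)
  rb <- readExpressionMatrix(tf[["baseline"]])
  expect_equal(dim(rb), dim(trialExpression(co, "baseline")))
  obs <- !is.na(rb)
  expect_equal(rb[obs], trialExpression(co, "baseline")[obs])
  clin <- readClinicalTable(tf[["clinical"]])
  expect_equal(nrow(clin), nrow(visitTable(co)))
  expect_equal(readGmt(tf[["signatures"]]),
               groundTruth(co)$signatureSets)
})
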
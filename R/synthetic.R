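#' Simulation configuration for synthetic trial data
#'
#' Fixes every parameter of the synthetic reference-cohort and trial
#' generators. Defaults emulate the design of a small placebo-controlled
#' trial in diffuse cutaneous systemic sclerosis: 7 abatacept / 3 placebo
#' patients (6 + 2 biopsied), three intrinsic subsets with 100-gene
#' signatures shifted by 2.0 log2 units over sd-0.5 noise, four healthy
#' controls, eight scheduled visits, and an mRSS model with drug effect
#' -9.8, disease-duration slope -0.9, patient-intercept sd 6 and residual
#' sd 3.
#'
#' @param seed integer seed (mandatory; every generator draw derives from
#'   it).
#' @param nGenes total genes simulated.
#' @param nSignatureGenes signature genes per intrinsic subset.
#' @param effectSize log2 shift of a subset's signature genes in its own
#'   samples.
#' @param noiseSd Gaussian noise sd (log-ratio scale).
#' @param nReferencePerSubset reference samples per subset.
#' @param includeLimited also simulate a "limited" reference subset (its own
#'   signature block), for testing subset exclusion.
#' @param nPatientsPerArm named vector, patients randomized per arm.
#' @param nBiopsiedPerArm named vector, patients with paired biopsies per
#'   arm.
#' @param nHealthy healthy-control samples.
#' @param improverFraction named vector, target improver fraction per arm
#'   (used only when `forceImproverFraction`).
#' @param forceImproverFraction impose improver flags at the configured
#'   fractions instead of deriving them from the generated mRSS
#'   trajectories.
#' @param signatureDecay post-treatment shift of an improver's subset
#'   signature toward background in treated improvers (log2 units).
#' @param nonImproverDrift mild post-treatment increase of the subset
#'   signature in non-improvers and placebo patients.
#' @param mrssIntercept,durationSlope,drugEffect,visitTrend fixed effects of
#'   the generating mRSS model (mrss = intercept + slope x duration +
#'   drugEffect x drug + visitTrend x visit + patient intercept + noise,
#'   rounded and truncated to \[0, 51\]).
#' @param interceptSd,residualSd random-intercept and residual sd of the
#'   mRSS model.
#' @param durationMean,durationSd named vectors, disease-duration
#'   distribution per arm (years from first non-Raynaud symptom).
#' @param missingnessRate completely-at-random missingness rate applied when
#'   expression files are emitted for the preprocessing chain.
#' @param heavyTails draw noise from a t distribution with 5 df (scaled to
#'   `noiseSd`) instead of Gaussian noise.
#' @return list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed,
    nGenes = 2000L, nSignatureGenes = 100L,
    effectSize = 2.0, noiseSd = 0.5,
    nReferencePerSubset = 30L, includeLimited = FALSE,
    nPatientsPerArm = c(abatacept = 7L, placebo = 3L),
    nBiopsiedPerArm = c(abatacept = 6L, placebo = 2L),
    nHealthy = 4L,
    improverFraction = c(abatacept = 5 / 7, placebo = 1 / 3),
    forceImproverFraction = FALSE,
    signatureDecay = 1.5, nonImproverDrift = 0.3,
    mrssIntercept = 36, durationSlope = -0.9, drugEffect = -9.8,
    visitTrend = -0.1, interceptSd = 6, residualSd = 3,
    durationMean = c(abatacept = 2.4, placebo = 8.8),
    durationSd = c(abatacept = 1.6, placebo = 3.8),
    missingnessRate = 0.02, heavyTails = FALSE) {
  .stopIfNot(!missing(seed) && is.numeric(seed) && length(seed) == 1,
             "an integer seed is mandatory")
  .stopIfNot(noiseSd >= 0 && interceptSd >= 0 && residualSd >= 0 &&
             all(durationSd >= 0), "all sds must be >= 0")
  .stopIfNot(all(improverFraction >= 0 & improverFraction <= 1) &&
             missingnessRate >= 0 && missingnessRate <= 1,
             "fractions must lie in [0, 1]")
  nSubsets <- 3L + as.integer(isTRUE(includeLimited))
  .stopIfNot(nSignatureGenes * nSubsets <= nGenes,
             "signature genes exceed the simulated gene count")
  .stopIfNot(all(nBiopsiedPerArm <= nPatientsPerArm),
             "cannot biopsy more patients than randomized")
  cfg <- as.list(environment())
  cfg$nSubsets <- nSubsets
  class(cfg) <- "SimulationConfig"
  cfg
}

.subsetNames <- function(cfg)
  c("inflammatory", "fibroproliferative", "normal-like",
    if (isTRUE(cfg$includeLimited)) "limited")

.simNoise <- function(cfg, n) {
  if (isTRUE(cfg$heavyTails))
    stats::rt(n, df = 5) * cfg$noiseSd / sqrt(5 / 3)
  else stats::rnorm(n, 0, cfg$noiseSd)
}

.geneIds <- function(cfg) sprintf("G%05d", seq_len(cfg$nGenes))

# signature gene blocks: consecutive, one block per subset
.signatureSets <- function(cfg) {
  subsets <- .subsetNames(cfg)
  genes <- .geneIds(cfg)
  sets <- lapply(seq_along(subsets), function(i)
    genes[((i - 1L) * cfg$nSignatureGenes + 1L):(i * cfg$nSignatureGenes)])
  names(sets) <- paste0(subsets, "_signature")
  sets
}

#' Generate a labelled reference cohort
#'
#' Background genes are drawn from Normal(0, `noiseSd`); each subset's
#' signature genes are shifted by `+effectSize` in that subset's samples.
#' Output is bit-reproducible for a fixed configuration.
#'
#' @param cfg a [simulationConfig()].
#' @return a [ReferenceCohort-class] whose `signatureSets` hold the
#'   generating signature gene sets (the ground truth).
#' @export
generateReferenceCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  subsets <- .subsetNames(cfg)
  sets <- .signatureSets(cfg)
  genes <- .geneIds(cfg)
  nPer <- cfg$nReferencePerSubset
  ids <- unlist(lapply(subsets, function(s)
    sprintf("REF_%s_%02d", gsub("-", "", s), seq_len(nPer))))
  labels <- stats::setNames(rep(subsets, each = nPer), ids)
  m <- matrix(.simNoise(cfg, cfg$nGenes * length(ids)),
              nrow = cfg$nGenes, dimnames = list(genes, ids))
  for (s in subsets) {
    sig <- sets[[paste0(s, "_signature")]]
    m[sig, names(labels)[labels == s]] <-
      m[sig, names(labels)[labels == s]] + cfg$effectSize
  }
  new("ReferenceCohort", expression = m, labels = labels,
      signatureSets = sets)
}

# one expression sample for a patient profile: the patient's own subset
# signature genes sit at `level` log2 units above background
.drawSample <- function(cfg, subset, level) {
  sets <- .signatureSets(cfg)
  x <- .simNoise(cfg, cfg$nGenes)
  names(x) <- .geneIds(cfg)
  if (subset %in% .subsetNames(cfg))
    x[sets[[paste0(subset, "_signature")]]] <-
      x[sets[[paste0(subset, "_signature")]]] + level
  x
}

#' Generate a paired-biopsy trial cohort with known ground truth
#'
#' Simulates the randomized trial: patients per arm with disease durations
#' drawn per arm, eight-visit mRSS trajectories from the configured linear
#' mixed model (rounded, truncated to \[0, 51\]), improver flags derived from
#' the trajectories (>= 30 % relative decrease at the final visit) unless
#' `forceImproverFraction` imposes the configured fractions, and paired
#' baseline/post expression for the biopsied patients. Baseline biopsies are
#' drawn from the patient's intrinsic-subset model (improvers are mostly
#' inflammatory); post-treatment biopsies of treated improvers have their
#' subset signature decayed toward background by `signatureDecay`, while
#' non-improvers and placebo patients drift mildly upward.
#'
#' @param cfg a [simulationConfig()].
#' @return a [TrialCohort-class]; `groundTruth()` exposes the generating
#'   parameters, per-patient subset and improver flags, and the signature
#'   gene sets.
#' @export
generateTrialCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  .stopIfNot(setequal(names(cfg$nPatientsPerArm), c("abatacept", "placebo")),
             "arms must be abatacept and placebo")
  set.seed(cfg$seed + 1L)
  arms <- rep(names(cfg$nPatientsPerArm), cfg$nPatientsPerArm)
  nPat <- length(arms)
  pid <- sprintf("P%02d", seq_len(nPat))
  duration <- pmax(0.3, stats::rnorm(nPat, cfg$durationMean[arms],
                                     cfg$durationSd[arms]))
  drug <- as.integer(arms == "abatacept")
  bInt <- stats::rnorm(nPat, 0, cfg$interceptSd)

  visits <- expand.grid(patient_id = pid, visit = seq_len(8L),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  visits <- visits[order(match(visits$patient_id, pid), visits$visit), ]
  i <- match(visits$patient_id, pid)
  mu <- cfg$mrssIntercept + cfg$durationSlope * duration[i] +
    cfg$drugEffect * drug[i] + cfg$visitTrend * visits$visit + bInt[i]
  visits$mrss <- pmin(51L, pmax(0L, as.integer(round(
    mu + stats::rnorm(nrow(visits), 0, cfg$residualSd)))))
  visits$visit_day <- defaultVisitSchedule()[visits$visit]
  visits <- visits[, c("patient_id", "visit", "visit_day", "mrss")]
  rownames(visits) <- NULL

  if (isTRUE(cfg$forceImproverFraction)) {
    improver <- logical(nPat)
    for (a in unique(arms)) {
      idx <- which(arms == a)
      nImp <- round(cfg$improverFraction[[a]] * length(idx))
      improver[sample(idx, nImp)] <- TRUE
    }
    # make the trajectories consistent with the imposed flags: improvers
    # ramp to a ~40 % final decrease, non-improvers to ~10 %
    for (k in seq_len(nPat)) {
      v <- which(visits$patient_id == pid[k])
      b1 <- max(visits$mrss[v][1L], 10L)
      target <- as.integer(round(b1 * if (improver[k]) 0.6 else 0.9))
      traj <- b1 + (target - b1) * (seq_len(8L) - 1L) / 7 +
        stats::rnorm(8L, 0, 1)
      traj <- pmin(51L, pmax(0L, as.integer(round(traj))))
      traj[1L] <- b1; traj[8L] <- target
      visits$mrss[v] <- traj
    }
  } else {
    base <- visits$mrss[visits$visit == 1L][match(pid,
              visits$patient_id[visits$visit == 1L])]
    final <- visits$mrss[visits$visit == 8L][match(pid,
              visits$patient_id[visits$visit == 8L])]
    # a zero-baseline trajectory cannot improve by a relative criterion
    improver <- base > 0 & (base - final) / pmax(base, 1L) >= 0.3 - 1e-12
  }

  # intrinsic subset per patient: improvers mostly inflammatory
  subset <- character(nPat)
  for (k in seq_len(nPat)) {
    subset[k] <- if (improver[k])
      sample(c("inflammatory", "normal-like"), 1L, prob = c(0.8, 0.2))
    else sample(c("normal-like", "inflammatory", "fibroproliferative"), 1L,
                prob = c(0.6, 0.2, 0.2))
  }

  biopsied <- unlist(lapply(names(cfg$nBiopsiedPerArm), function(a)
    pid[arms == a][seq_len(cfg$nBiopsiedPerArm[[a]])]))
  genes <- .geneIds(cfg)
  baseline <- post <- matrix(NA_real_, cfg$nGenes, length(biopsied),
    dimnames = list(genes, NULL))
  bIds <- paste0(biopsied, "_BL"); pIds <- paste0(biopsied, "_24W")
  colnames(baseline) <- bIds; colnames(post) <- pIds
  for (k in seq_along(biopsied)) {
    w <- match(biopsied[k], pid)
    baseline[, k] <- .drawSample(cfg, subset[w], cfg$effectSize)
    postLevel <- if (improver[w] && drug[w] == 1L)
      max(0, cfg$effectSize - cfg$signatureDecay)
    else cfg$effectSize + cfg$nonImproverDrift
    post[, k] <- .drawSample(cfg, subset[w], postLevel)
  }
  healthy <- matrix(.simNoise(cfg, cfg$nGenes * cfg$nHealthy), cfg$nGenes,
                    dimnames = list(genes,
                      sprintf("HC%02d", seq_len(cfg$nHealthy))))

  patients <- data.frame(patient_id = pid, arm = arms,
    disease_duration = duration,
    baseline_sample = ifelse(pid %in% biopsied, paste0(pid, "_BL"), NA),
    post_sample = ifelse(pid %in% biopsied, paste0(pid, "_24W"), NA),
    improver = improver, subset = subset, stringsAsFactors = FALSE)

  truth <- list(parameters = unclass(cfg),
                improver = stats::setNames(improver, pid),
                subset = stats::setNames(subset, pid),
                signatureSets = .signatureSets(cfg))
  new("TrialCohort", baseline = baseline, post = post, healthy = healthy,
      patients = patients, visits = visits, truth = truth)
}

#' Inject completely-at-random missingness
#'
#' Replaces the given fraction of entries by `NA`, guaranteeing that every
#' row and column keeps at least one observed value (so the matrix stays
#' imputable).
#'
#' @param m numeric matrix.
#' @param rate fraction of cells set missing.
#' @param seed optional integer seed.
#' @return matrix with `NA` entries.
#' @export
injectMissing <- function(m, rate, seed = NULL) {
  m <- .asExprMatrix(m)
  .stopIfNot(rate >= 0 && rate <= 1, "rate must lie in [0, 1]")
  if (rate == 0 || length(m) == 0L) return(m)
  if (!is.null(seed)) set.seed(seed)
  idx <- which(stats::runif(length(m)) < rate)
  out <- m
  out[idx] <- NA
  # restore one observed value in any fully-missing row or column
  badRows <- which(rowSums(!is.na(out)) == 0L)
  for (r in badRows) out[r, sample.int(ncol(out), 1L)] <- m[r, ]
  badCols <- which(colSums(!is.na(out)) == 0L)
  for (cc in badCols) out[sample.int(nrow(out), 1L), cc] <- m[, cc]
  out
}

#' Write a reference cohort to pipeline-ready files
#'
#' @param ref a [ReferenceCohort-class].
#' @param dir output directory (created if needed).
#' @return named character vector of files written, invisibly.
#' @export
writeReferenceCohort <- function(ref, dir) {
  stopifnot(is(ref, "ReferenceCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(expression = file.path(dir, "reference_expression.tsv"),
         labels = file.path(dir, "reference_labels.csv"),
         signatures = file.path(dir, "signatures.gmt"))
  writeExpressionMatrix(expressionMatrix(ref), f[["expression"]])
  utils::write.csv(data.frame(sample_id = names(subsetLabels(ref)),
                              label = unname(subsetLabels(ref))),
                   f[["labels"]], row.names = FALSE, quote = FALSE)
  writeGmt(ref@signatureSets, f[["signatures"]])
  invisible(f)
}

#' Write a trial cohort to pipeline-ready files
#'
#' Emits the formats the pipeline consumes: baseline/post/healthy expression
#' TSV (with the configured completely-at-random missingness injected, so the
#' preprocessing chain has work to do), a long-format clinical CSV, a patient
#' table CSV, and the true signature gene sets as GMT.
#'
#' @param cohort a [TrialCohort-class].
#' @param dir output directory (created if needed).
#' @param missingnessRate fraction of expression cells set missing before
#'   writing (default: the generating configuration's rate, else 0).
#' @param seed integer seed for the missingness draw (default: derived from
#'   the generating configuration).
#' @return named character vector of files written, invisibly.
#' @export
writeTrialCohort <- function(cohort, dir, missingnessRate = NULL,
                             seed = NULL) {
  stopifnot(is(cohort, "TrialCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pars <- groundTruth(cohort)$parameters
  if (is.null(missingnessRate))
    missingnessRate <- if (!is.null(pars)) pars$missingnessRate else 0
  if (is.null(seed)) seed <- if (!is.null(pars)) pars$seed + 2L else 0L
  f <- c(baseline = file.path(dir, "expression_baseline.tsv"),
         post = file.path(dir, "expression_post.tsv"),
         healthy = file.path(dir, "expression_healthy.tsv"),
         clinical = file.path(dir, "clinical.csv"),
         patients = file.path(dir, "patients.csv"),
         signatures = file.path(dir, "signatures.gmt"))
  writeExpressionMatrix(
    injectMissing(trialExpression(cohort, "baseline"), missingnessRate, seed),
    f[["baseline"]])
  writeExpressionMatrix(
    injectMissing(trialExpression(cohort, "post"), missingnessRate, seed + 1L),
    f[["post"]])
  writeExpressionMatrix(trialExpression(cohort, "healthy"), f[["healthy"]])
  pts <- patientTable(cohort)
  vis <- merge(visitTable(cohort),
               pts[, c("patient_id", "arm", "disease_duration")],
               by = "patient_id")
  vis <- vis[order(match(vis$patient_id, pts$patient_id), vis$visit), ]
  utils::write.csv(vis, f[["clinical"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(pts, f[["patients"]], row.names = FALSE, quote = FALSE)
  writeGmt(groundTruth(cohort)$signatureSets, f[["signatures"]])
  invisible(f)
}
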
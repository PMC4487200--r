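#' Pipeline run configuration
#'
#' Declarative configuration for [runPipeline()]. Either a
#' [simulationConfig()] (the run starts by simulating and writing its own
#' inputs) or a list of input paths must be given.
#'
#' @param outputDir directory for intermediate artifacts and the report.
#' @param seed integer seed governing every stochastic stage.
#' @param simulate optional [simulationConfig()].
#' @param inputs optional named list of paths: `baseline`, `post`, `healthy`
#'   (optional), `clinical`, `patients`, `signatures` (GMT),
#'   `referenceExpression`, `referenceLabels`.
#' @param stages stages to run, in fixed order; any subset of
#'   `c("preprocess", "subtype", "improver", "markers", "enrichment",
#'   "clinical")`. Omitted stages are reported as skipped.
#' @param preprocess a [preprocessConfig()].
#' @param gseaParams named list of overrides passed to [gsea()]
#'   (e.g. `nPerm`, `weight`, `minSize`).
#' @param ssgseaAlpha ssGSEA rank-weighting exponent.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(outputDir, seed = 1L, simulate = NULL, inputs = NULL,
                      stages = c("preprocess", "subtype", "improver",
                                 "markers", "enrichment", "clinical"),
                      preprocess = preprocessConfig(),
                      gseaParams = list(), ssgseaAlpha = 0.75) {
  .stopIfNot(!is.null(simulate) || !is.null(inputs),
             "either a simulation config or input paths are required")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "SimulationConfig"))
  allStages <- c("preprocess", "subtype", "improver", "markers",
                 "enrichment", "clinical")
  .stopIfNot(all(stages %in% allStages), "unknown stage name")
  cfg <- list(outputDir = outputDir, seed = as.integer(seed),
              simulate = simulate, inputs = inputs,
              stages = intersect(allStages, stages),
              preprocess = preprocess, gseaParams = gseaParams,
              ssgseaAlpha = ssgseaAlpha)
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full molecular-response pipeline
#'
#' Executes, in fixed order: input simulation (when configured) or loading;
#' preprocessing of the combined expression matrix (all biopsy samples plus
#' healthy controls share one centering distribution); intrinsic subset
#' assignment of the biopsy samples by nearest centroid; improver
#' classification from the mRSS trajectories plus the improver-by-arm exact
#' test; paired marker selection between baseline and post-treatment improver
#' samples; enrichment (GSEA over the signature sets and an ssGSEA
#' projection); and the clinical layer (baseline summary, mixed model,
#' signature deltas). Intermediate artifacts are written to `outputDir`; the
#' report cross-links, per biopsied patient, improver status, baseline subset
#' call and inflammatory-signature delta.
#'
#' On a stage failure the report accumulated so far is written before the
#' error propagates.
#'
#' @param config a [runConfig()].
#' @return the run report (named list, also written as `report.json`),
#'   invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = list(seed = config$seed,
                                   stages = config$stages),
                 warnings = character(0))
  state <- new.env(parent = emptyenv())
  finish <- function(report) {
    path <- file.path(config$outputDir, "report.json")
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    report
  }
  runStage <- function(name, fun) {
    if (!name %in% c(config$stages, "input")) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible())
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
      finish(report)
      stop("stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    report$stages[[name]] <<- c(list(status = "done"), res)
    invisible()
  }

  runStage("input", function() {
    if (!is.null(config$simulate)) {
      ref <- generateReferenceCohort(config$simulate)
      cohort <- generateTrialCohort(config$simulate)
      inDir <- file.path(config$outputDir, "input")
      writeReferenceCohort(ref, inDir)
      files <- writeTrialCohort(cohort, inDir)
      state$refExpr <- expressionMatrix(ref)
      state$refLabels <- subsetLabels(ref)
      state$baseline <- readExpressionMatrix(files[["baseline"]])
      state$post <- readExpressionMatrix(files[["post"]])
      state$healthy <- trialExpression(cohort, "healthy")
      state$clinical <- readClinicalTable(files[["clinical"]])
      state$patients <- utils::read.csv(files[["patients"]])
      state$sets <- readGmt(files[["signatures"]])
      list(mode = "simulated",
           nPatients = nrow(state$patients),
           nGenes = nrow(state$baseline))
    } else {
      ins <- config$inputs
      state$baseline <- readExpressionMatrix(ins$baseline)
      state$post <- readExpressionMatrix(ins$post)
      state$healthy <- if (!is.null(ins$healthy))
        readExpressionMatrix(ins$healthy) else
        matrix(numeric(0), nrow(state$baseline), 0,
               dimnames = list(rownames(state$baseline), NULL))
      state$clinical <- readClinicalTable(ins$clinical)
      state$patients <- utils::read.csv(ins$patients)
      state$sets <- readGmt(ins$signatures)
      state$refExpr <- readExpressionMatrix(ins$referenceExpression)
      state$refLabels <- readSubsetLabels(ins$referenceLabels)
      list(mode = "loaded", nPatients = nrow(state$patients),
           nGenes = nrow(state$baseline))
    }
  })

  runStage("preprocess", function() {
    combined <- cbind(state$baseline, state$post, state$healthy)
    pp <- preprocessExpression(combined, annotation = NULL,
                               config = config$preprocess)
    state$expr <- pp$matrix
    writeExpressionMatrix(state$expr,
                          file.path(config$outputDir, "expression_processed.tsv"))
    pp$report
  })
  if (is.null(state$expr))   # preprocessing skipped: use raw, imputed input
    state$expr <- imputeMissingKnn(cbind(state$baseline, state$post,
                                         state$healthy))

  runStage("subtype", function() {
    centroids <- buildSubsetCentroids(state$refExpr, labels = state$refLabels,
                                      genes = rownames(state$expr))
    biopsy <- setdiff(colnames(state$expr), colnames(state$healthy))
    calls <- assignIntrinsicSubsets(state$expr[, biopsy, drop = FALSE],
                                    centroids)
    state$calls <- subsetCall(calls)
    utils::write.csv(state$calls,
                     file.path(config$outputDir, "subset_calls.csv"),
                     row.names = FALSE)
    list(nGenesCentroid = length(geneList(centroids)),
         nDroppedGenes = centroids@nDroppedGenes,
         calls = state$calls)
  })

  runStage("improver", function() {
    imp <- classifyImprovers(state$clinical)
    imp$arm <- state$patients$arm[match(imp$patient_id,
                                        state$patients$patient_id)]
    state$improvers <- imp
    tab <- table(factor(imp$arm, c("abatacept", "placebo")),
                 factor(imp$improver, c(TRUE, FALSE)))
    ft <- fisherExact2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    utils::write.csv(imp, file.path(config$outputDir, "improvers.csv"),
                     row.names = FALSE)
    list(improvers = imp, table = as.data.frame(tab),
         fisher_p = ft$p)
  })

  .improverPairs <- function() {
    pts <- state$patients
    imp <- state$improvers
    pts$improver <- imp$improver[match(pts$patient_id, imp$patient_id)]
    pts <- pts[!is.na(pts$baseline_sample) & !is.na(pts$post_sample) &
               pts$improver & pts$arm == "abatacept", , drop = FALSE]
    pts
  }

  runStage("markers", function() {
    pts <- .improverPairs()
    if (nrow(pts) < 2L) stop("fewer than 2 improver pairs for marker selection")
    ca <- classAssignment(pts$baseline_sample, pts$post_sample,
                          pairs = stats::setNames(pts$post_sample,
                                                  pts$baseline_sample))
    mk <- twoClassMarkerSelection(state$expr, ca, paired = TRUE)
    state$markers <- mk
    utils::write.table(mk, file.path(config$outputDir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(nGenes = nrow(mk), nSignificant = sum(mk$significant))
  })

  runStage("enrichment", function() {
    pts <- .improverPairs()
    if (nrow(pts) < 2L) stop("fewer than 2 improver pairs for enrichment")
    ca <- classAssignment(pts$baseline_sample, pts$post_sample)
    args <- c(list(m = state$expr[, c(pts$baseline_sample, pts$post_sample)],
                   classes = ca, sets = state$sets,
                   seed = config$seed), config$gseaParams)
    if (is.null(args$minSize)) args$minSize <- 15
    gs <- do.call(gsea, args)
    utils::write.table(gs, file.path(config$outputDir, "gsea.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    proj <- ssgseaProject(state$expr, state$sets,
                          alpha = config$ssgseaAlpha)
    utils::write.table(data.frame(set = rownames(proj), proj,
                                  check.names = FALSE),
                       file.path(config$outputDir, "ssgsea.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$gsea <- gs
    list(gsea = gs[, c("set", "size", "es", "nes", "p", "q", "significant")],
         nSignificant = sum(gs$significant),
         ssgseaSets = nrow(proj))
  })

  runStage("clinical", function() {
    pts <- state$patients
    summ <- cohortSummary(pts[, setdiff(names(pts),
                                        c("improver", "subset"))])
    fit <- fitMrssMixedModel(applyLocf(state$clinical), pts)
    infl <- grep("inflammatory", names(state$sets), value = TRUE)[1]
    crossLink <- NULL
    if (!is.na(infl) && !is.null(state$calls)) {
      biop <- pts[!is.na(pts$baseline_sample) & !is.na(pts$post_sample), ]
      base <- scoreSignature(state$expr, state$sets[[infl]],
                             biop$baseline_sample)
      post <- scoreSignature(state$expr, state$sets[[infl]],
                             biop$post_sample)
      crossLink <- data.frame(
        patient_id = biop$patient_id, arm = biop$arm,
        improver = state$improvers$improver[match(biop$patient_id,
                                     state$improvers$patient_id)],
        baseline_subset = state$calls$call[match(biop$baseline_sample,
                                                 state$calls$sample_id)],
        signature_delta = post$score - base$score,
        stringsAsFactors = FALSE)
      utils::write.csv(crossLink,
                       file.path(config$outputDir, "patient_crosslink.csv"),
                       row.names = FALSE)
    }
    deltaTest <- if (!is.null(crossLink) && sum(crossLink$improver) >= 2) {
      imp <- crossLink[crossLink$improver, ]
      ib <- scoreSignature(state$expr, state$sets[[infl]],
        pts$baseline_sample[match(imp$patient_id, pts$patient_id)])$score
      ip <- scoreSignature(state$expr, state$sets[[infl]],
        pts$post_sample[match(imp$patient_id, pts$patient_id)])$score
      compareSignatureGroups(ip, ib, paired = TRUE)
    } else NULL
    list(summary = summ,
         mixedModel = list(coefficients = fixedEffects(fit),
                           varIntercept = fit@varIntercept,
                           varResidual = fit@varResidual,
                           dfMethod = fit@dfMethod),
         crossLink = crossLink,
         improverSignatureDeltaTest = deltaTest)
  })

  report$timestamp <- format(Sys.time(), tz = "UTC")
  invisible(finish(report))
}
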
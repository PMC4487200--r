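#' Per-subset gene-expression centroids
#'
#' Gene-by-subset matrix of mean expression over a labelled reference cohort,
#' used for nearest-centroid intrinsic subset classification. Rows are the
#' intrinsic genes shared between the reference platform and the study
#' platform; columns are subset labels (e.g. inflammatory, fibroproliferative,
#' normal-like).
#'
#' @slot centroids numeric matrix, genes x subsets, no missing values.
#' @slot nDroppedGenes integer, intrinsic genes requested but absent from the
#'   reference matrix (dropped during construction).
#'
#' @seealso [buildSubsetCentroids()], [assignIntrinsicSubsets()]
#' @export
setClass("SubsetCentroids",
  representation(centroids = "matrix", nDroppedGenes = "integer"),
  prototype(nDroppedGenes = 0L)
)

setValidity("SubsetCentroids", function(object) {
  m <- object@centroids
  if (!is.numeric(m)) return("centroids must be a numeric matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("centroid genes must be uniquely named")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    return("subset labels must be uniquely named")
  if (anyNA(m)) return("centroids must not contain missing values")
  if (length(object@nDroppedGenes) != 1L || object@nDroppedGenes < 0L)
    return("nDroppedGenes must be a single non-negative integer")
  TRUE
})

#' Intrinsic subset calls for a set of samples
#'
#' Result of nearest-centroid classification: per sample, the Spearman rho and
#' two-sided p-value against every subset centroid, the winning subset, and
#' the margin between the best and second-best rho.
#'
#' @slot rho numeric matrix, samples x subsets, Spearman correlation
#'   coefficients in \[-1, 1\].
#' @slot p numeric matrix, samples x subsets, two-sided p-values in (0, 1\].
#' @slot calls data.frame with columns `sample_id`, `call`, `margin`,
#'   `n_genes`.
#'
#' @seealso [assignIntrinsicSubsets()]
#' @export
setClass("SubsetCalls",
  representation(rho = "matrix", p = "matrix", calls = "data.frame")
)

setValidity("SubsetCalls", function(object) {
  if (!identical(dim(object@rho), dim(object@p)))
    return("rho and p matrices must have identical dimensions")
  if (nrow(object@calls) != nrow(object@rho))
    return("one call row per sample required")
  if (!all(c("sample_id", "call", "margin") %in% names(object@calls)))
    return("calls must contain sample_id, call and margin")
  if (any(object@rho < -1 - 1e-12 | object@rho > 1 + 1e-12, na.rm = TRUE))
    return("rho values must lie in [-1, 1]")
  if (any(object@p <= 0 | object@p > 1, na.rm = TRUE))
    return("p-values must lie in (0, 1]")
  ok <- vapply(seq_len(nrow(object@rho)), function(i) {
    r <- object@rho[i, ]
    abs(r[object@calls$call[i]] - max(r)) < 1e-12
  }, logical(1))
  if (!all(ok)) return("each call must be a subset attaining the maximal rho")
  TRUE
})

#' Labelled reference cohort for centroid construction
#'
#' Expression matrix (genes x reference samples) plus the intrinsic subset
#' label of every sample, as produced by molecular subtyping of a reference
#' skin-biopsy cohort, and (for synthetic cohorts) the generating signature
#' gene sets.
#'
#' @slot expression numeric matrix, genes x samples.
#' @slot labels named character vector, sample id -> subset label.
#' @slot signatureSets list of character vectors of signature genes per
#'   subset (empty for real cohorts with unknown ground truth).
#'
#' @seealso [generateReferenceCohort()], [buildSubsetCentroids()]
#' @export
setClass("ReferenceCohort",
  representation(expression = "matrix", labels = "character",
                 signatureSets = "list"),
  prototype(signatureSets = list())
)

setValidity("ReferenceCohort", function(object) {
  if (is.null(colnames(object@expression)))
    return("expression matrix must have sample names")
  if (is.null(names(object@labels)))
    return("labels must be named by sample id")
  if (!all(names(object@labels) %in% colnames(object@expression)))
    return("every labelled sample must exist in the expression matrix")
  if (length(object@labels) == 0L)
    return("at least one labelled sample required")
  TRUE
})

#' Paired-biopsy trial cohort with clinical trajectories
#'
#' Container for a randomized-trial dataset: baseline and post-treatment
#' expression matrices over a shared gene list, one clinical row per patient
#' (arm, disease duration, links to biopsy samples), a long-format visit table
#' of mRSS values, optional healthy-control expression, and — for synthetic
#' cohorts — the generating ground truth.
#'
#' @slot baseline numeric matrix, genes x baseline biopsy samples.
#' @slot post numeric matrix, genes x post-treatment biopsy samples.
#' @slot healthy numeric matrix, genes x healthy-control samples (may have
#'   zero columns).
#' @slot patients data.frame, one row per randomized patient: `patient_id`,
#'   `arm`, `disease_duration`, `baseline_sample`, `post_sample` (NA if not
#'   biopsied) and any covariates.
#' @slot visits data.frame, one row per patient-visit: `patient_id`,
#'   `visit`, `visit_day`, `mrss`.
#' @slot truth list of generating parameters and per-patient/sample ground
#'   truth (empty for real data).
#'
#' @seealso [generateTrialCohort()], [runPipeline()]
#' @export
setClass("TrialCohort",
  representation(baseline = "matrix", post = "matrix", healthy = "matrix",
                 patients = "data.frame", visits = "data.frame",
                 truth = "list"),
  prototype(truth = list())
)

setValidity("TrialCohort", function(object) {
  need <- c("patient_id", "arm", "disease_duration", "baseline_sample",
            "post_sample")
  if (!all(need %in% names(object@patients)))
    return(paste("patients must contain:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@patients$patient_id))
    return("patient ids must be unique")
  if (!all(object@patients$arm %in% c("abatacept", "placebo")))
    return("arm must be abatacept or placebo")
  if (!all(c("patient_id", "visit", "visit_day", "mrss") %in%
           names(object@visits)))
    return("visits must contain patient_id, visit, visit_day, mrss")
  bs <- stats::na.omit(object@patients$baseline_sample)
  ps <- stats::na.omit(object@patients$post_sample)
  if (!all(bs %in% colnames(object@baseline)))
    return("every linked baseline sample must exist in the baseline matrix")
  if (!all(ps %in% colnames(object@post)))
    return("every linked post sample must exist in the post matrix")
  if (!identical(rownames(object@baseline), rownames(object@post)))
    return("baseline and post matrices must share one gene list")
  TRUE
})

#' Random-intercept mixed-model fit for longitudinal mRSS
#'
#' Fixed-effect table (estimate, standard error, t-interval confidence bounds
#' and p-value per coefficient) plus the restricted-maximum-likelihood
#' variance components of a patient-level random-intercept model.
#'
#' @slot coefficients data.frame with columns `term`, `estimate`, `se`, `df`,
#'   `lower`, `upper`, `p`.
#' @slot varIntercept non-negative numeric, patient random-intercept variance.
#' @slot varResidual non-negative numeric, residual variance.
#' @slot dfMethod character, the degrees-of-freedom convention used.
#' @slot nObs integer, observations used.
#' @slot nPatients integer, patients used.
#'
#' @seealso [fitMrssMixedModel()]
#' @export
setClass("MixedModelFit",
  representation(coefficients = "data.frame", varIntercept = "numeric",
                 varResidual = "numeric", dfMethod = "character",
                 nObs = "integer", nPatients = "integer")
)

setValidity("MixedModelFit", function(object) {
  cf <- object@coefficients
  need <- c("term", "estimate", "se", "df", "lower", "upper", "p")
  if (!all(need %in% names(cf)))
    return(paste("coefficients must contain:", paste(need, collapse = ", ")))
  if (any(cf$lower > cf$upper)) return("confidence bounds must be ordered")
  if (object@varIntercept < 0 || object@varResidual < 0)
    return("variance components must be non-negative")
  TRUE
})

setMethod("show", "SubsetCentroids", function(object) {
  cat("SubsetCentroids:", nrow(object@centroids), "genes x",
      ncol(object@centroids), "subsets\n")
  cat("  subsets:", paste(colnames(object@centroids), collapse = ", "), "\n")
  if (object@nDroppedGenes > 0L)
    cat("  ", object@nDroppedGenes,
        "requested intrinsic genes absent from reference (dropped)\n")
})

setMethod("show", "SubsetCalls", function(object) {
  cat("SubsetCalls for", nrow(object@calls), "samples over",
      ncol(object@rho), "subsets\n")
  print(table(object@calls$call))
})

setMethod("show", "ReferenceCohort", function(object) {
  cat("ReferenceCohort:", nrow(object@expression), "genes x",
      ncol(object@expression), "samples\n")
  print(table(object@labels))
})

setMethod("show", "TrialCohort", function(object) {
  cat("TrialCohort:", nrow(object@patients), "patients (",
      sum(object@patients$arm == "abatacept"), "abatacept /",
      sum(object@patients$arm == "placebo"), "placebo ),",
      sum(!is.na(object@patients$baseline_sample)), "biopsied\n")
  cat("  expression:", nrow(object@baseline), "genes;",
      ncol(object@healthy), "healthy controls;",
      nrow(object@visits), "visit records\n")
})

setMethod("show", "MixedModelFit", function(object) {
  cat("Linear mixed model (random patient intercept, REML)\n")
  cat("  ", object@nObs, "observations from", object@nPatients, "patients;",
      "df method:", object@dfMethod, "\n")
  cf <- object@coefficients
  cf[-1] <- lapply(cf[-1], function(x) signif(x, 4))
  print(cf, row.names = FALSE)
  cat("  random-intercept variance:", signif(object@varIntercept, 4),
      "; residual variance:", signif(object@varResidual, 4), "\n")
})
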
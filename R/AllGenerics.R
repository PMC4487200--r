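#' Accessors for package classes
#'
#' Small accessor family: `centroidMatrix()` returns the gene-by-subset
#' centroid matrix, `geneList()` the ordered shared gene list,
#' `subsetLabels()` the subset names of a centroid set or the per-sample
#' labels of a reference cohort, `subsetCall()` the per-sample call table,
#' `rhoMatrix()` / `pMatrix()` the per-subset correlation statistics,
#' `expressionMatrix()` the expression slot of a cohort, and
#' `fixedEffects()` the fixed-effect table of a mixed-model fit.
#'
#' @param object an object of the documented classes.
#' @return The slot content as a base matrix, character vector or data.frame.
#' @name accessors
#' @aliases centroidMatrix geneList subsetLabels subsetCall rhoMatrix pMatrix
#'   expressionMatrix fixedEffects
#' @examples
#' ref <- generateReferenceCohort(simulationConfig(seed = 1,
#'   nGenes = 200, nReferencePerSubset = 4))
#' ctr <- buildSubsetCentroids(ref)
#' head(geneList(ctr))
#' dim(centroidMatrix(ctr))
NULL

#' @rdname accessors
#' @export
setGeneric("centroidMatrix", function(object) standardGeneric("centroidMatrix"))
#' @rdname accessors
#' @export
setGeneric("geneList", function(object) standardGeneric("geneList"))
#' @rdname accessors
#' @export
setGeneric("subsetLabels", function(object) standardGeneric("subsetLabels"))
#' @rdname accessors
#' @export
setGeneric("subsetCall", function(object) standardGeneric("subsetCall"))
#' @rdname accessors
#' @export
setGeneric("rhoMatrix", function(object) standardGeneric("rhoMatrix"))
#' @rdname accessors
#' @export
setGeneric("pMatrix", function(object) standardGeneric("pMatrix"))
#' @rdname accessors
#' @export
setGeneric("expressionMatrix", function(object)
  standardGeneric("expressionMatrix"))
#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))

#' @rdname accessors
setMethod("centroidMatrix", "SubsetCentroids",
          function(object) object@centroids)
#' @rdname accessors
setMethod("geneList", "SubsetCentroids",
          function(object) rownames(object@centroids))
#' @rdname accessors
setMethod("subsetLabels", "SubsetCentroids",
          function(object) colnames(object@centroids))
#' @rdname accessors
setMethod("subsetLabels", "ReferenceCohort", function(object) object@labels)
#' @rdname accessors
setMethod("subsetCall", "SubsetCalls", function(object) object@calls)
#' @rdname accessors
setMethod("rhoMatrix", "SubsetCalls", function(object) object@rho)
#' @rdname accessors
setMethod("pMatrix", "SubsetCalls", function(object) object@p)
#' @rdname accessors
setMethod("expressionMatrix", "ReferenceCohort",
          function(object) object@expression)
#' @rdname accessors
setMethod("fixedEffects", "MixedModelFit",
          function(object) object@coefficients)

#' @rdname accessors
#' @export
setGeneric("patientTable", function(object) standardGeneric("patientTable"))
#' @rdname accessors
#' @export
setGeneric("visitTable", function(object) standardGeneric("visitTable"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
setMethod("patientTable", "TrialCohort", function(object) object@patients)
#' @rdname accessors
setMethod("visitTable", "TrialCohort", function(object) object@visits)
#' @rdname accessors
setMethod("groundTruth", "TrialCohort", function(object) object@truth)
#' @rdname accessors
setMethod("groundTruth", "ReferenceCohort",
          function(object) list(labels = object@labels,
                                signatureSets = object@signatureSets))

#' Baseline / post / healthy expression of a trial cohort
#'
#' @param object a [TrialCohort-class].
#' @param which one of `"baseline"`, `"post"`, `"healthy"`, or `"all"`
#'   (column-bound baseline + post + healthy).
#' @return genes x samples numeric matrix.
#' @export
setGeneric("trialExpression", function(object, which = "baseline")
  standardGeneric("trialExpression"))

#' @rdname trialExpression
setMethod("trialExpression", "TrialCohort", function(object, which = "baseline") {
  which <- match.arg(which, c("baseline", "post", "healthy", "all"))
  switch(which,
    baseline = object@baseline,
    post = object@post,
    healthy = object@healthy,
    all = cbind(object@baseline, object@post, object@healthy))
})
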
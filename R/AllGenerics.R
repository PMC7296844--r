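#' @name accessors
#' @title Accessors for rewardConn objects
#' @description Small accessor generics so user code never touches slots.
#' @param object a rewardConn S4 object.
#' @param ... passed to methods.
NULL

#' @rdname accessors
#' @export
setGeneric("trials", function(object, ...) standardGeneric("trials"))
#' @rdname accessors
#' @export
setGeneric("qids", function(object, ...) standardGeneric("qids"))
#' @rdname accessors
#' @export
setGeneric("covariates", function(object, ...) standardGeneric("covariates"))
#' @rdname accessors
#' @export
setGeneric("taskConfig", function(object, ...) standardGeneric("taskConfig"))
#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(object, ...) standardGeneric("freeEnergy"))
#' @rdname accessors
#' @export
setGeneric("posteriorMean", function(object, ...) standardGeneric("posteriorMean"))
#' @rdname accessors
#' @export
setGeneric("posteriorCov", function(object, ...) standardGeneric("posteriorCov"))
#' @rdname accessors
#' @export
setGeneric("winner", function(object, ...) standardGeneric("winner"))
#' @rdname accessors
#' @export
setGeneric("ibicValues", function(object, ...) standardGeneric("ibicValues"))
#' @rdname accessors
#' @export
setGeneric("nParams", function(object, ...) standardGeneric("nParams"))
#' @rdname accessors
#' @export
setGeneric("varianceExplained", function(object, ...) standardGeneric("varianceExplained"))

#' @rdname accessors
#' @export
setMethod("trials", "SubjectRecord", function(object, ...) object@trials)
#' @rdname accessors
#' @export
setMethod("qids", "SubjectRecord", function(object, ...) object@qids)
#' @rdname accessors
#' @export
setMethod("qids", "Cohort", function(object, ...)
  vapply(object, function(s) s@qids, numeric(1)))
#' @rdname accessors
#' @export
setMethod("covariates", "SubjectRecord", function(object, ...)
  data.frame(subject_id = object@subjectId, qids = object@qids,
             hads_a = object@hadsA, age = object@age, sex = object@sex,
             site = object@site, mde = object@mde,
             stringsAsFactors = FALSE))
#' @rdname accessors
#' @export
setMethod("covariates", "Cohort", function(object, ...)
  do.call(rbind, lapply(object, covariates)))
#' @rdname accessors
#' @export
setMethod("taskConfig", "Cohort", function(object, ...) object@config)
#' @rdname accessors
#' @export
setMethod("freeEnergy", "DCMPosterior", function(object, ...) object@freeEnergy)
#' @rdname accessors
#' @export
setMethod("freeEnergy", "PEBResult", function(object, ...) object@freeEnergy)
#' @rdname accessors
#' @export
setMethod("posteriorMean", "DCMPosterior", function(object, ...) object@mu)
#' @rdname accessors
#' @export
setMethod("posteriorMean", "PEBResult", function(object, ...) object@beta)
#' @rdname accessors
#' @export
setMethod("posteriorCov", "DCMPosterior", function(object, ...) object@cov)
#' @rdname accessors
#' @export
setMethod("posteriorCov", "PEBResult", function(object, ...) object@cov)
#' @rdname accessors
#' @export
setMethod("winner", "ModelComparison", function(object, ...) object@winner)
#' @rdname accessors
#' @export
setMethod("ibicValues", "ModelComparison", function(object, ...) object@ibic)
#' @rdname accessors
#' @export
setMethod("nParams", "RLModel", function(object, ...) object@nParams)
#' @rdname accessors
#' @export
setMethod("varianceExplained", "DCMPosterior", function(object, ...)
  object@explainedVariance)

setMethod("show", "TaskConfig", function(object) {
  cat("TaskConfig:", object@nTrials, "trials (",
      object@nChoiceTrials, "choice ), arms",
      object@pRewardHigh, "/", object@pRewardLow,
      ", TR", object@tr, "s x", object@nScans, "scans\n")
})

setMethod("show", "SubjectRecord", function(object) {
  cat("SubjectRecord", object@subjectId, ":", nrow(object@trials),
      "trials; QIDS", object@qids, "; HADS-A", object@hadsA,
      ";", object@mde, "MDE\n")
})

setMethod("show", "Cohort", function(object) {
  cat("Cohort of", length(object), "subjects;",
      object@config@nTrials, "trials each\n")
})

setMethod("show", "RLModel", function(object) {
  cat(sprintf("RL model %d (%d params): %s\n", object@modelId, object@nParams,
              paste(object@paramNames, collapse = ", ")))
})

setMethod("show", "ModelComparison", function(object) {
  cat("Model comparison (iBIC, lower is better):\n")
  print(round(object@ibic, 1))
  cat("winner: model", object@winner, "\n")
})

setMethod("show", "DCMPosterior", function(object) {
  cat(sprintf(
    "DCMPosterior: F = %.2f, %.1f%% variance explained, %d iterations%s\n",
    object@freeEnergy, object@explainedVariance, object@iterations,
    if (object@converged) "" else " (not converged)"))
})

setMethod("show", "PEBResult", function(object) {
  cat(sprintf("PEBResult: %d covariates x %d parameters, F = %.2f\n",
              nrow(object@beta), ncol(object@beta), object@freeEnergy))
})

setMethod("show", "BMAResult", function(object) {
  cat("Bayesian model average over", length(object@weights), "models\n")
})
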
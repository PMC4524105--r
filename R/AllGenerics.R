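#' @name accessors
#' @title Accessors for mpmrad classes
#' @description Small accessor generics; slot access from user code is
#'   discouraged.
#' @param x an mpmrad object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @rdname accessors
#' @export
setMethod("imageData", "ModalityVolume", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setMethod("spacing", "ModalityVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "DwiSeries", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("modalityName", function(x) standardGeneric("modalityName"))
#' @rdname accessors
#' @export
setMethod("modalityName", "ModalityVolume", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setMethod("bValues", "DwiSeries", function(x) x@bValues)
#' @rdname accessors
#' @export
setMethod("bValues", "PatientStudy", function(x) x@dwi@bValues)

#' @rdname accessors
#' @export
setGeneric("bVolumes", function(x) standardGeneric("bVolumes"))
#' @rdname accessors
#' @export
setMethod("bVolumes", "DwiSeries", function(x) x@volumes)

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setMethod("patientId", "PatientStudy", function(x) x@patientId)

#' @rdname accessors
#' @export
setGeneric("dwiSeries", function(x) standardGeneric("dwiSeries"))
#' @rdname accessors
#' @export
setMethod("dwiSeries", "PatientStudy", function(x) x@dwi)

#' @rdname accessors
#' @export
setGeneric("glandMask", function(x) standardGeneric("glandMask"))
#' @rdname accessors
#' @export
setMethod("glandMask", "PatientStudy", function(x) x@glandMask)

#' @rdname accessors
#' @export
setGeneric("tumourMask", function(x) standardGeneric("tumourMask"))
#' @rdname accessors
#' @export
setMethod("tumourMask", "PatientStudy", function(x) x@tumourMask)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "PatientStudy", function(x) x@groundTruth)

#' @rdname accessors
#' @export
setGeneric("derivedVolumes", function(x) standardGeneric("derivedVolumes"))
#' @rdname accessors
#' @export
setMethod("derivedVolumes", "PatientStudy", function(x) x@derived)

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "TextureFeatureMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setMethod("featureNames", "TextureFeatureMatrix",
          function(x) colnames(x@values))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setMethod("sampleLabels", "TextureFeatureMatrix", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @rdname accessors
#' @export
setMethod("patientIds", "TextureFeatureMatrix", function(x) x@patientIds)
#' @rdname accessors
#' @export
setMethod("patientIds", "EvaluationReport", function(x) x@patientIds)

#' @rdname accessors
#' @export
setGeneric("sampleCoords", function(x) standardGeneric("sampleCoords"))
#' @rdname accessors
#' @export
setMethod("sampleCoords", "TextureFeatureMatrix", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("rankedFeatures", function(x) standardGeneric("rankedFeatures"))
#' @rdname accessors
#' @export
setMethod("rankedFeatures", "SelectionResult", function(x) x@rankedFeatures)

#' @rdname accessors
#' @export
setGeneric("bestM", function(x) standardGeneric("bestM"))
#' @rdname accessors
#' @export
setMethod("bestM", "SelectionResult", function(x) x@bestM)

#' @rdname accessors
#' @export
setGeneric("bestSubset", function(x) standardGeneric("bestSubset"))
#' @rdname accessors
#' @export
setMethod("bestSubset", "SelectionResult", function(x) x@bestSubset)

#' @rdname accessors
#' @export
setGeneric("scoreCurve", function(x) standardGeneric("scoreCurve"))
#' @rdname accessors
#' @export
setMethod("scoreCurve", "SelectionResult", function(x) x@scoreCurve)

#' @rdname accessors
#' @export
setGeneric("selectionCriterion", function(x) standardGeneric("selectionCriterion"))
#' @rdname accessors
#' @export
setMethod("selectionCriterion", "SelectionResult", function(x) x@criterion)
#' @rdname accessors
#' @export
setMethod("selectionCriterion", "TextureFeatureModel", function(x) x@criterion)

#' @rdname accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))
#' @rdname accessors
#' @export
setMethod("modelName", "TextureFeatureModel", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("modelModalities", function(x) standardGeneric("modelModalities"))
#' @rdname accessors
#' @export
setMethod("modelModalities", "TextureFeatureModel", function(x) x@modalities)

#' @rdname accessors
#' @export
setGeneric("perModalitySubsets",
           function(x) standardGeneric("perModalitySubsets"))
#' @rdname accessors
#' @export
setMethod("perModalitySubsets", "TextureFeatureModel",
          function(x) x@perModalitySubsets)

#' @rdname accessors
#' @export
setGeneric("finalSubset", function(x) standardGeneric("finalSubset"))
#' @rdname accessors
#' @export
setMethod("finalSubset", "TextureFeatureModel", function(x) x@finalSubset)

#' @rdname accessors
#' @export
setGeneric("modelClassifier", function(x) standardGeneric("modelClassifier"))
#' @rdname accessors
#' @export
setMethod("modelClassifier", "TextureFeatureModel", function(x) x@classifier)

#' @rdname accessors
#' @export
setGeneric("pooledMetrics", function(x) standardGeneric("pooledMetrics"))
#' @rdname accessors
#' @export
setMethod("pooledMetrics", "EvaluationReport", function(x) x@pooled)

#' @rdname accessors
#' @export
setGeneric("perPatientMetrics", function(x) standardGeneric("perPatientMetrics"))
#' @rdname accessors
#' @export
setMethod("perPatientMetrics", "EvaluationReport", function(x) x@perPatient)

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setMethod("rocPoints", "EvaluationReport", function(x) x@roc)

setMethod("show", "PhantomConfig", function(object) {
  cat("PhantomConfig:", object@nPatients, "patients,",
      paste(object@gridShape, collapse = "x"), "grid @",
      paste(object@voxelSpacing, collapse = "x"), "mm\n")
  cat("  b-values:", paste(object@bValues, collapse = ", "), "s/mm^2\n")
  cat(sprintf("  D healthy [%g, %g], tumour [%g, %g] mm^2/s\n",
              object@dHealthy[1], object@dHealthy[2],
              object@dTumour[1], object@dTumour[2]))
  cat(sprintf("  noise sigma %g, tumour fraction %g, seed %d\n",
              object@noiseSigma, object@tumourFraction, object@seed))
})

setMethod("show", "ModalityVolume", function(object) {
  cat(sprintf("ModalityVolume '%s': %s @ %s mm, range [%.4g, %.4g]\n",
              object@name, paste(dim(object@data), collapse = "x"),
              paste(object@spacing, collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "DwiSeries", function(object) {
  cat(sprintf("DwiSeries: %d b-values (%s s/mm^2), grid %s\n",
              length(object@bValues),
              paste(object@bValues, collapse = ", "),
              paste(dim(object@volumes[[1]]), collapse = "x")))
})

setMethod("show", "PatientStudy", function(object) {
  cat(sprintf("PatientStudy '%s': grid %s, gland %d voxels, tumour %d voxels\n",
              object@patientId,
              paste(dim(object@glandMask), collapse = "x"),
              sum(object@glandMask), sum(object@tumourMask)))
  if (length(object@derived))
    cat("  derived:", paste(names(object@derived), collapse = ", "), "\n")
})

setMethod("show", "TextureFeatureMatrix", function(object) {
  cat(sprintf("TextureFeatureMatrix: %d samples x %d features, %d patients, %d cancerous\n",
              nrow(object@values), ncol(object@values),
              length(unique(object@patientIds)),
              sum(object@labels == "cancer")))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): best m = %d of %d ranked features\n",
              object@criterion, object@bestM, length(object@rankedFeatures)))
})

setMethod("show", "TextureFeatureModel", function(object) {
  cat(sprintf("TextureFeatureModel %s: %s; criterion %s, target %s\n",
              object@name, paste(object@modalities, collapse = "+"),
              object@criterion, object@target))
  cat(sprintf("  stage-1 sizes: %s; final subset: %d features\n",
              paste(vapply(object@perModalitySubsets, length, 1L),
                    collapse = ", "),
              length(object@finalSubset)))
})

setMethod("show", "EvaluationReport", function(object) {
  p <- object@pooled
  cat(sprintf(
    "EvaluationReport: %d samples (%d cancerous), %d patients\n",
    object@nSamples, object@nCancerous, nrow(object@perPatient)))
  for (m in c("sensitivity", "specificity", "accuracy", "auc")) {
    e <- p[[m]]
    cat(sprintf("  %-11s %.3f [%.3f, %.3f]\n", m, e$estimate,
                e$ci[1], e$ci[2]))
  }
})
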
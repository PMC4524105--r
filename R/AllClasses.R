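#' @useDynLib mpmrad, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats fft rnorm runif sd quantile wilcox.test setNames
#' @importFrom utils head read.delim write.table
NULL

MODALITY_NAMES <- c("T2w", "ADC", "CHB-DWI", "CDI", "b1", "b2", "b3", "b4")

#' Configuration of the synthetic MP-MRI phantom cohort
#'
#' Holds every parameter of the synthetic multi-patient phantom: grid
#' geometry, the acquired b-values, tissue diffusion-coefficient ranges,
#' baseline-signal range, the fractional T2w signal drop inside lesions,
#' the Rician noise scale, the target tumour fraction of the gland, the
#' per-patient lesion-count prior, and the RNG seed. Diffusion
#' coefficients are in mm^2/s, spacing in mm, b-values in s/mm^2.
#'
#' @slot nPatients number of patients in the cohort.
#' @slot gridShape integer vector of voxels per axis (DWI grid).
#' @slot voxelSpacing mm per axis.
#' @slot bValues acquired b-values, strictly increasing, starting at 0.
#' @slot dHealthy,dTumour length-2 ranges the per-patient diffusion
#'   coefficients are drawn from; tumour range must lie strictly below
#'   the healthy range (restricted diffusion).
#' @slot s0Range range of the per-patient baseline signal.
#' @slot t2wTumourDrop fractional T2w signal reduction inside lesions.
#' @slot noiseSigma Rician noise scale (same units as signal).
#' @slot tumourFraction target fraction of gland voxels that are tumour.
#' @slot lesionCountProbs probabilities of 0, 1, 2 lesions per patient.
#' @slot seed integer RNG seed.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(
    nPatients = "integer",
    gridShape = "integer",
    voxelSpacing = "numeric",
    bValues = "numeric",
    dHealthy = "numeric",
    dTumour = "numeric",
    s0Range = "numeric",
    t2wTumourDrop = "numeric",
    noiseSigma = "numeric",
    tumourFraction = "numeric",
    lesionCountProbs = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (length(object@bValues) < 2L || object@bValues[1] != 0 ||
      any(diff(object@bValues) <= 0))
    msg <- c(msg, "bValues must be strictly increasing and start at 0")
  if (!(max(object@dTumour) < min(object@dHealthy)) || min(object@dTumour) <= 0)
    msg <- c(msg, "need 0 < dTumour < dHealthy (restricted diffusion in tumour)")
  if (object@tumourFraction <= 0 || object@tumourFraction >= 0.1)
    msg <- c(msg, "tumourFraction must be in (0, 0.1)")
  if (length(object@lesionCountProbs) != 3L ||
      abs(sum(object@lesionCountProbs) - 1) > 1e-8)
    msg <- c(msg, "lesionCountProbs must be 3 probabilities summing to 1")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A single scalar image volume with its grid geometry
#'
#' @slot name modality name, one of T2w, ADC, CHB-DWI, CDI, b1..b4
#'   (other names are allowed for intermediate maps such as S0).
#' @slot data 3-D numeric array.
#' @slot spacing mm per axis.
#' @exportClass ModalityVolume
setClass("ModalityVolume",
  representation(name = "character", data = "array", spacing = "numeric")
)

setValidity("ModalityVolume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values (mm)")
  TRUE
})

#' A co-registered diffusion-weighted series indexed by b-value
#'
#' One scalar volume per acquired b-value, all on the same grid. The
#' signal model is the mono-exponential decay S(b) = S0 * exp(-b * D).
#'
#' @slot bValues acquired b-values in s/mm^2, ascending.
#' @slot volumes list of 3-D arrays, one per b-value.
#' @slot spacing mm per axis.
#' @exportClass DwiSeries
setClass("DwiSeries",
  representation(bValues = "numeric", volumes = "list", spacing = "numeric")
)

setValidity("DwiSeries", function(object) {
  if (length(object@bValues) != length(object@volumes) ||
      length(object@bValues) < 2L)
    return("need one volume per b-value and at least 2 b-values")
  if (any(diff(object@bValues) <= 0))
    return("bValues must be strictly increasing")
  d <- dim(object@volumes[[1]])
  for (v in object@volumes) {
    if (!identical(dim(v), d)) return("all volumes must share one grid")
    if (any(v < 0)) return("volumes must be non-negative")
  }
  TRUE
})

#' All imaging data for one (synthetic or clinical) patient
#'
#' @slot patientId identifier string.
#' @slot dwi the acquired [DwiSeries-class].
#' @slot t2w the T2-weighted [ModalityVolume-class] (possibly on a finer
#'   grid than the DWI series; see [resampleToGrid()]).
#' @slot glandMask,tumourMask logical 3-D arrays on the DWI grid;
#'   the tumour mask is nested inside the gland mask.
#' @slot derived named list of derived [ModalityVolume-class] objects
#'   (ADC, CHB-DWI, CDI, ...), filled by [deriveModalities()].
#' @slot groundTruth list of generator parameters for phantom studies
#'   (empty for clinical data).
#' @exportClass PatientStudy
setClass("PatientStudy",
  representation(
    patientId = "character",
    dwi = "DwiSeries",
    t2w = "ModalityVolume",
    glandMask = "array",
    tumourMask = "array",
    derived = "list",
    groundTruth = "list"
  )
)

setValidity("PatientStudy", function(object) {
  d <- dim(object@dwi@volumes[[1]])
  if (!identical(dim(object@glandMask), d) ||
      !identical(dim(object@tumourMask), d))
    return("masks must live on the DWI grid")
  if (any(object@tumourMask & !object@glandMask))
    return("tumour mask must be nested inside the gland mask")
  TRUE
})

#' Samples-by-features texture matrix with provenance
#'
#' One row per sliding window whose centre lies inside the gland mask.
#' Feature names encode provenance as "modality/family/name[/detail]",
#' e.g. "ADC/glcm/contrast/d45". Labels are a factor with levels
#' healthy/cancer; the positive class is "cancer".
#'
#' @slot values numeric matrix, samples x features.
#' @slot labels factor of per-sample class labels (healthy/cancer).
#' @slot patientIds character vector of per-sample patient identifiers.
#' @slot coords integer matrix (x, y, z) of window-centre voxel indices
#'   (1-based, analysis grid).
#' @exportClass TextureFeatureMatrix
setClass("TextureFeatureMatrix",
  representation(
    values = "matrix",
    labels = "factor",
    patientIds = "character",
    coords = "matrix"
  )
)

setValidity("TextureFeatureMatrix", function(object) {
  n <- nrow(object@values)
  if (length(object@labels) != n || length(object@patientIds) != n ||
      nrow(object@coords) != n)
    return("labels, patientIds and coords must have one entry per sample")
  if (!identical(levels(object@labels), c("healthy", "cancer")))
    return("labels must be a factor with levels healthy, cancer")
  cn <- colnames(object@values)
  if (is.null(cn) || anyDuplicated(cn))
    return("feature names must be present and unique")
  if (anyNA(object@values)) return("feature values must not contain NA")
  TRUE
})

#' Result of criterion-driven subset-size selection along an mRMR ranking
#'
#' @slot criterion one of sensitivity, specificity, auc.
#' @slot rankedFeatures feature names in mRMR order.
#' @slot bestM selected subset size.
#' @slot bestSubset the first bestM ranked names.
#' @slot scoreCurve data.frame with one row per candidate subset size m
#'   (columns m, score, plus all metrics).
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(
    criterion = "character",
    rankedFeatures = "character",
    bestM = "integer",
    bestSubset = "character",
    scoreCurve = "data.frame"
  )
)

setValidity("SelectionResult", function(object) {
  if (object@bestM < 1L || object@bestM > length(object@rankedFeatures))
    return("bestM must be within 1..length(rankedFeatures)")
  if (!identical(object@bestSubset,
                 object@rankedFeatures[seq_len(object@bestM)]))
    return("bestSubset must be a prefix of rankedFeatures")
  TRUE
})

#' A trained window classifier with its standardization and threshold
#'
#' Wraps an RBF support vector machine trained on standardized features.
#' Standardization statistics (centre/scale) come from the training fold
#' only and are stored so they can be applied verbatim to held-out data.
#'
#' @slot fit the underlying [e1071::svm] fit.
#' @slot features the feature names the classifier uses, in order.
#' @slot centre,scale training-fold standardization statistics.
#' @slot threshold operating threshold on the decision score.
#' @slot flip 1 or -1; orients decision scores so larger means cancer.
#' @exportClass WindowClassifier
setClass("WindowClassifier",
  representation(
    fit = "ANY",
    features = "character",
    centre = "numeric",
    scale = "numeric",
    threshold = "numeric",
    flip = "numeric"
  )
)

#' A texture feature model: modality combination, subsets, classifier
#'
#' The six published combinations are TFM1 = {T2w, ADC}; TFM2 = TFM1 +
#' CHB-DWI; TFM3 = {T2w, CDI}; TFM4 = {T2w, ADC, CDI}; TFM5 = TFM4 +
#' CHB-DWI; TFM6 = TFM5 + the four individual b-value images.
#'
#' @slot name model name (TFM1..TFM6 or custom).
#' @slot modalities the modality names the model combines.
#' @slot criterion selection criterion (sensitivity/specificity/auc).
#' @slot target metric maximized when picking the final subset size
#'   (defaults to the criterion; may differ, e.g. specificity-driven
#'   selection targeting AUC).
#' @slot perModalitySubsets named list: modality -> stage-1 selected
#'   feature names.
#' @slot finalSubset feature names after the combined (stage-3) selection.
#' @slot stage1 named list of stage-1 [SelectionResult-class]s.
#' @slot stage3 the combined-stage [SelectionResult-class].
#' @slot classifier a [WindowClassifier-class] trained on the full
#'   cohort with finalSubset.
#' @exportClass TextureFeatureModel
setClass("TextureFeatureModel",
  representation(
    name = "character",
    modalities = "character",
    criterion = "character",
    target = "character",
    perModalitySubsets = "list",
    finalSubset = "character",
    stage1 = "list",
    stage3 = "ANY",
    classifier = "ANY"
  )
)

setValidity("TextureFeatureModel", function(object) {
  pool <- unlist(object@perModalitySubsets, use.names = FALSE)
  if (!all(object@finalSubset %in% pool))
    return("finalSubset must be a subset of the union of per-modality subsets")
  if (!all(object@modalities %in% MODALITY_NAMES))
    return("unknown modality name")
  TRUE
})

#' Leave-one-patient-out evaluation report
#'
#' @slot perPatient data.frame of per-patient sensitivity, specificity,
#'   accuracy, auc (NA where undefined, e.g. sensitivity for a patient
#'   without cancerous samples) plus confusion counts.
#' @slot pooled named list of pooled sensitivity, specificity, accuracy,
#'   auc, each with a 95% patient-bootstrap confidence interval.
#' @slot roc data.frame of ordered (fpr, tpr) points.
#' @slot scores,labels,patientIds pooled held-out decision scores with
#'   truth and provenance.
#' @slot nSamples,nCancerous sample counts.
#' @slot config list capturing the evaluation configuration (provenance).
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(
    perPatient = "data.frame",
    pooled = "list",
    roc = "data.frame",
    scores = "numeric",
    labels = "factor",
    patientIds = "character",
    nSamples = "integer",
    nCancerous = "integer",
    config = "list"
  )
)

setValidity("EvaluationReport", function(object) {
  r <- object@roc
  if (nrow(r)) {
    if (any(diff(r$fpr) < -1e-12) || any(diff(r$tpr) < -1e-12))
      return("ROC must be monotone non-decreasing")
    if (abs(r$fpr[1]) > 1e-12 || abs(r$tpr[1]) > 1e-12 ||
        abs(r$fpr[nrow(r)] - 1) > 1e-12 || abs(r$tpr[nrow(r)] - 1) > 1e-12)
      return("ROC must run from (0,0) to (1,1)")
  }
  TRUE
})
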
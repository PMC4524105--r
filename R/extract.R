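#' Extract the 96-feature texture vector per modality over a study
#'
#' Slides a window over every gland voxel (optionally strided in-plane)
#' of the analysis (DWI) grid and computes, per requested modality, the
#' 96 texture features: 4 first-order statistics, 18 GLCM statistics in
#' each of 4 directions, 12 Gabor filter-bank responses (3 frequencies
#' x 4 orientations, image-level filtering with mean-magnitude pooling
#' over the window) and 8 Kirsch compass gradients (maximum absolute
#' response over the window). Windows are 2-D (slice-wise): slices are
#' thick relative to the in-plane spacing, so 3-D windows would be
#' strongly anisotropic.
#'
#' GLCM quantization uses `levels` grey levels min-max scaled per
#' modality over the gland (not per window), so inter-window contrast
#' is preserved. A window is labelled cancerous iff its centre voxel is
#' in the tumour mask. Modalities are ordered canonically (T2w, ADC,
#' CHB-DWI, CDI, b1..b4) regardless of the order requested.
#'
#' @param study a [PatientStudy-class] after [deriveModalities()].
#' @param modalities modality names to extract; default all eight.
#' @param window odd window edge length in pixels.
#' @param stride in-plane stride in pixels between window centres.
#' @param levels GLCM grey levels.
#' @param frequencies,orientations Gabor bank parameters.
#' @return A [TextureFeatureMatrix-class] with 96 features per modality.
#' @export
extractFeatures <- function(study, modalities = MODALITY_NAMES,
                            window = 3L, stride = 1L, levels = 16L,
                            frequencies = GABOR_FREQUENCIES,
                            orientations = GABOR_ORIENTATIONS) {
  stopIfNot(is(study, "PatientStudy"), "study must be a PatientStudy")
  stopIfNot(window %% 2 == 1 && window >= 3, "window must be odd and >= 3")
  modalities <- MODALITY_NAMES[MODALITY_NAMES %in% modalities]
  half <- (window - 1L) %/% 2L
  gland <- study@glandMask
  tumour <- study@tumourMask
  shape <- dim(gland)

  keep <- array(FALSE, dim = shape)
  keep[seq(1L, shape[1], by = stride), seq(1L, shape[2], by = stride), ] <- TRUE
  centres <- which(gland & keep, arr.ind = TRUE)
  colnames(centres) <- c("x", "y", "z")
  stopIfNot(nrow(centres) > 0, "no gland voxels on the sampling grid")
  labels <- factor(ifelse(tumour[centres], "cancer", "healthy"),
                   levels = c("healthy", "cancer"))

  blocks <- lapply(modalities, function(mod) {
    vol <- studyModality(study, mod)
    dat <- vol@data
    if (!identical(dim(dat), shape))
      dat <- imageData(resampleToGrid(vol, shape, study@dwi@spacing,
                                      mode = "linear"))
    rng <- range(dat[gland])
    quant <- quantizeMinMax(dat, rng, levels)
    out <- matrix(NA_real_, nrow(centres), 96L)
    for (z in sort(unique(centres[, "z"]))) {
      sel <- which(centres[, "z"] == z)
      rows <- centres[sel, "x"]; cols <- centres[sel, "y"]
      rawSlice <- dat[, , z]
      tex <- cppSlidingTexture(rawSlice, quant[, , z], rows, cols,
                               half, levels)
      gab <- gaborResponses(rawSlice, frequencies, orientations)
      gabPooled <- vapply(gab, function(m) boxMean2D(m, half)[cbind(rows, cols)],
                          numeric(length(sel)))
      kir <- kirschResponses(rawSlice)
      kirPooled <- vapply(kir, function(m) boxMax2D(abs(m), half)[cbind(rows, cols)],
                          numeric(length(sel)))
      if (length(sel) == 1L) {
        gabPooled <- matrix(gabPooled, nrow = 1L)
        kirPooled <- matrix(kirPooled, nrow = 1L)
      }
      out[sel, ] <- cbind(tex, gabPooled, kirPooled)
    }
    out
  })
  values <- do.call(cbind, blocks)
  colnames(values) <- unlist(lapply(modalities, featureNamesForModality,
                                    frequencies = frequencies,
                                    orientations = orientations))
  new("TextureFeatureMatrix",
      values = values, labels = labels,
      patientIds = rep(study@patientId, nrow(values)),
      coords = centres)
}

#' Extract features for every study of a cohort
#'
#' Row-binds the per-study [extractFeatures()] results into one
#' [TextureFeatureMatrix-class] keyed by patient id.
#'
#' @param cohort list of [PatientStudy-class] objects (derived
#'   modalities already attached, or set `derive = TRUE`).
#' @param derive if TRUE, run [deriveModalities()] on each study first.
#' @inheritParams extractFeatures
#' @param ... further arguments passed to [extractFeatures()].
#' @return A [TextureFeatureMatrix-class].
#' @export
extractCohortFeatures <- function(cohort, modalities = MODALITY_NAMES,
                                  derive = FALSE, ...) {
  mats <- lapply(cohort, function(st) {
    if (derive) st <- deriveModalities(st)
    extractFeatures(st, modalities = modalities, ...)
  })
  new("TextureFeatureMatrix",
      values = do.call(rbind, lapply(mats, function(m) m@values)),
      labels = factor(unlist(lapply(mats, function(m) as.character(m@labels))),
                      levels = c("healthy", "cancer")),
      patientIds = unlist(lapply(mats, function(m) m@patientIds)),
      coords = do.call(rbind, lapply(mats, function(m) m@coords)))
}

#' Subset a feature matrix by feature names and/or samples
#'
#' @param fm a [TextureFeatureMatrix-class].
#' @param features feature names to keep (default all).
#' @param samples integer or logical sample index (default all).
#' @return A [TextureFeatureMatrix-class].
#' @export
subsetFeatures <- function(fm, features = featureNames(fm),
                           samples = seq_len(nrow(fm@values))) {
  missing <- setdiff(features, colnames(fm@values))
  if (length(missing))
    stop("unknown feature(s): ", paste(head(missing, 3), collapse = ", "),
         call. = FALSE)
  new("TextureFeatureMatrix",
      values = fm@values[samples, features, drop = FALSE],
      labels = fm@labels[samples],
      patientIds = fm@patientIds[samples],
      coords = fm@coords[samples, , drop = FALSE])
}

#' Combine per-modality feature matrices with aligned samples
#'
#' Validates that all matrices describe the same windows (same patient
#' ids and centre coordinates, in the same order) and binds their
#' feature columns. The offending modality is named on misalignment.
#'
#' @param fmList named list of [TextureFeatureMatrix-class] objects.
#' @return A single [TextureFeatureMatrix-class].
#' @export
combineFeatureMatrices <- function(fmList) {
  stopIfNot(length(fmList) >= 1, "need at least one feature matrix")
  ref <- fmList[[1]]
  for (nm in names(fmList)[-1]) {
    m <- fmList[[nm]]
    if (!identical(m@patientIds, ref@patientIds) ||
        !identical(unname(m@coords), unname(ref@coords)) ||
        !identical(as.character(m@labels), as.character(ref@labels)))
      stop("feature matrix '", nm, "' is not sample-aligned with '",
           names(fmList)[1], "'", call. = FALSE)
  }
  new("TextureFeatureMatrix",
      values = do.call(cbind, lapply(fmList, function(m) m@values)),
      labels = ref@labels, patientIds = ref@patientIds, coords = ref@coords)
}
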
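writeNiftiVolume <- function(data, spacing, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
}

readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}

#' Write a patient study to a directory of NIfTI volumes
#'
#' Writes t2w.nii.gz, one dwi_b<value>.nii.gz per acquired b-value,
#' gland_mask.nii.gz, tumour_mask.nii.gz, any derived modalities, and a
#' study.json sidecar holding patient id, b-values and ground-truth
#' parameters.
#'
#' @param study a [PatientStudy-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeNiftiVolume(study@t2w@data, study@t2w@spacing,
                   file.path(dir, "t2w.nii.gz"))
  for (i in seq_along(study@dwi@bValues))
    writeNiftiVolume(study@dwi@volumes[[i]], study@dwi@spacing,
                     file.path(dir, sprintf("dwi_b%d.nii.gz",
                                            as.integer(study@dwi@bValues[i]))))
  writeNiftiVolume(study@glandMask * 1, study@dwi@spacing,
                   file.path(dir, "gland_mask.nii.gz"))
  writeNiftiVolume(study@tumourMask * 1, study@dwi@spacing,
                   file.path(dir, "tumour_mask.nii.gz"))
  for (nm in names(study@derived)) {
    v <- study@derived[[nm]]
    writeNiftiVolume(v@data, v@spacing,
                     file.path(dir, paste0("derived_", gsub("-", "", nm),
                                           ".nii.gz")))
  }
  sidecar <- list(patientId = study@patientId,
                  bValues = study@dwi@bValues,
                  derived = names(study@derived),
                  groundTruth = study@groundTruth)
  jsonlite::write_json(sidecar, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a patient study from a directory written by [writeStudy()]
#'
#' Round-trips losslessly for data and geometry. The b-values are
#' parsed from the sidecar (falling back to the file names) and
#' returned in ascending order. Missing volumes, inconsistent shapes
#' and mismatched spacings raise explicit errors.
#'
#' @param dir study directory.
#' @return A [PatientStudy-class].
#' @export
readStudy <- function(dir) {
  sidecarPath <- file.path(dir, "study.json")
  sidecar <- if (file.exists(sidecarPath))
    jsonlite::read_json(sidecarPath, simplifyVector = TRUE) else list()
  bFiles <- list.files(dir, "^dwi_b[0-9]+\\.nii\\.gz$")
  stopIfNot(length(bFiles) >= 2, paste0("no DWI series found in ", dir))
  bFromName <- as.numeric(sub("^dwi_b([0-9]+)\\.nii\\.gz$", "\\1", bFiles))
  b <- if (!is.null(sidecar$bValues)) sort(as.numeric(sidecar$bValues))
       else sort(bFromName)
  missing <- setdiff(b, bFromName)
  if (length(missing))
    stop("study in ", dir, " is missing DWI volume(s) for b = ",
         paste(missing, collapse = ", "), call. = FALSE)
  vols <- lapply(sort(b), function(bb)
    readNiftiVolume(file.path(dir, sprintf("dwi_b%d.nii.gz", as.integer(bb)))))
  shapes <- lapply(vols, function(v) dim(v$data))
  for (k in seq_along(vols)[-1]) {
    if (!identical(shapes[[k]], shapes[[1]]))
      stop("inconsistent DWI volume shapes in ", dir, call. = FALSE)
    if (max(abs(vols[[k]]$spacing - vols[[1]]$spacing)) > 1e-4)
      stop("inconsistent DWI voxel spacings in ", dir, call. = FALSE)
  }
  for (f in c("t2w.nii.gz", "gland_mask.nii.gz", "tumour_mask.nii.gz"))
    if (!file.exists(file.path(dir, f)))
      stop("study in ", dir, " is missing required volume ", f, call. = FALSE)
  t2wRaw <- readNiftiVolume(file.path(dir, "t2w.nii.gz"))
  gland <- readNiftiVolume(file.path(dir, "gland_mask.nii.gz"))
  tumour <- readNiftiVolume(file.path(dir, "tumour_mask.nii.gz"))
  stopIfNot(identical(dim(gland$data), shapes[[1]]) &&
            identical(dim(tumour$data), shapes[[1]]),
            "masks must share the DWI grid")
  dwi <- new("DwiSeries", bValues = sort(b),
             volumes = lapply(vols, `[[`, "data"),
             spacing = vols[[1]]$spacing)
  study <- new("PatientStudy",
      patientId = if (!is.null(sidecar$patientId)) sidecar$patientId
                  else basename(dir),
      dwi = dwi,
      t2w = new("ModalityVolume", name = "T2w", data = t2wRaw$data,
                spacing = t2wRaw$spacing),
      glandMask = array(gland$data > 0.5, dim(gland$data)),
      tumourMask = array(tumour$data > 0.5, dim(tumour$data)),
      derived = list(),
      groundTruth = if (!is.null(sidecar$groundTruth))
        sidecar$groundTruth else list())
  derivedFiles <- list.files(dir, "^derived_.*\\.nii\\.gz$")
  if (length(derivedFiles)) {
    nameMap <- c(ADC = "ADC", CHBDWI = "CHB-DWI", CDI = "CDI", S0 = "S0",
                 b1 = "b1", b2 = "b2", b3 = "b3", b4 = "b4")
    derived <- list()
    for (f in derivedFiles) {
      raw <- sub("^derived_(.*)\\.nii\\.gz$", "\\1", f)
      nm <- if (raw %in% names(nameMap)) nameMap[[raw]] else raw
      v <- readNiftiVolume(file.path(dir, f))
      derived[[nm]] <- new("ModalityVolume", name = nm, data = v$data,
                           spacing = v$spacing)
    }
    study@derived <- derived
  }
  study
}

#' Resample a modality volume onto a target grid
#'
#' Voxel i (1-based) is treated as centred at (i - 0.5) * spacing
#' (half-voxel-centre convention); both grids share the same physical
#' field of view. Intensities use trilinear interpolation; masks use
#' nearest-neighbour so they stay binary.
#'
#' @param volume a [ModalityVolume-class].
#' @param targetShape voxels per axis of the target grid.
#' @param targetSpacing mm per axis of the target grid.
#' @param mode "linear" for intensities, "nearest" for masks.
#' @return A [ModalityVolume-class] on the target grid.
#' @export
resampleToGrid <- function(volume, targetShape, targetSpacing,
                           mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  targetShape <- as.integer(targetShape)
  dat <- volume@data
  if (identical(dim(dat), targetShape))
    return(new("ModalityVolume", name = volume@name, data = dat,
               spacing = as.numeric(targetSpacing)))
  out <- if (mode == "linear") {
    trilinearResize(dat, targetShape)
  } else {
    d <- dim(dat)
    idx <- lapply(1:3, function(a) {
      s <- round((seq_len(targetShape[a]) - 0.5) * d[a] / targetShape[a] + 0.5)
      pmin(pmax(s, 1L), d[a])
    })
    dat[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  new("ModalityVolume", name = volume@name, data = array(out, targetShape),
      spacing = as.numeric(targetSpacing))
}

#' Persist a feature matrix as a tab-separated table
#'
#' One header row; columns patient_id, x, y, z, label, then the feature
#' columns (names keep their provenance encoding). A JSON sidecar with
#' the schema is written next to it.
#'
#' @param fm a [TextureFeatureMatrix-class].
#' @param path output .tsv path.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  df <- data.frame(patient_id = fm@patientIds,
                   fm@coords,
                   label = as.character(fm@labels),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(fm@values, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(columns = colnames(df), nSamples = nrow(df),
         nFeatures = ncol(fm@values),
         modalities = unique(modalityOfFeature(featureNames(fm)))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [writeFeatureMatrix()]
#'
#' @param path the .tsv path.
#' @return A [TextureFeatureMatrix-class].
#' @export
readFeatureMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  meta <- c("patient_id", "x", "y", "z", "label")
  stopIfNot(all(meta %in% colnames(df)), "not a feature-matrix TSV")
  feats <- setdiff(colnames(df), meta)
  new("TextureFeatureMatrix",
      values = as.matrix(df[, feats, drop = FALSE]),
      labels = factor(df$label, levels = c("healthy", "cancer")),
      patientIds = as.character(df$patient_id),
      coords = as.matrix(df[, c("x", "y", "z")]))
}
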
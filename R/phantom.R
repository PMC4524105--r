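#' Create a phantom cohort configuration
#'
#' Defaults emulate a realistic prostate MP-MRI acquisition: a DWI grid
#' of 64 x 64 x 16 voxels at 1.56 x 1.56 x 3 mm, b-values 0/100/400/1000
#' s/mm^2, per-patient healthy-tissue diffusion coefficients in
#' 1.4--2.0e-3 mm^2/s and tumour coefficients in 0.5--0.9e-3 mm^2/s
#' (restricted diffusion), a gland of roughly 25--30 cm^3, around 1.5%
#' of gland voxels cancerous, a 15% chance a patient has no lesion, and
#' Rician magnitude noise of scale 10 on a baseline signal near 1000.
#'
#' @param nPatients number of patients in the cohort.
#' @param gridShape voxels per axis of the DWI grid.
#' @param voxelSpacing mm per axis.
#' @param bValues acquired b-values (s/mm^2), ascending from 0.
#' @param dHealthy,dTumour ranges (mm^2/s) the per-patient diffusion
#'   coefficients are drawn from.
#' @param s0Range range of the per-patient baseline DWI signal.
#' @param t2wTumourDrop fractional T2w signal reduction inside lesions.
#' @param noiseSigma Rician noise scale; 0 gives noiseless studies.
#' @param tumourFraction target fraction of gland voxels that are tumour
#'   (for patients with at least one lesion).
#' @param lesionCountProbs probabilities of 0, 1 and 2 lesions.
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of it.
#' @return A [PhantomConfig-class] object.
#' @examples
#' cfg <- phantomConfig(nPatients = 2, gridShape = c(32, 32, 8), seed = 1)
#' study <- generateStudy(cfg, 1)
#' @export
phantomConfig <- function(nPatients = 20L,
                          gridShape = c(64L, 64L, 16L),
                          voxelSpacing = c(1.56, 1.56, 3),
                          bValues = c(0, 100, 400, 1000),
                          dHealthy = c(0.0014, 0.0020),
                          dTumour = c(0.0005, 0.0009),
                          s0Range = c(800, 1200),
                          t2wTumourDrop = 0.25,
                          noiseSigma = 10,
                          tumourFraction = 0.015,
                          lesionCountProbs = c(0.15, 0.55, 0.30),
                          seed = 42L) {
  new("PhantomConfig",
      nPatients = as.integer(nPatients),
      gridShape = as.integer(gridShape),
      voxelSpacing = as.numeric(voxelSpacing),
      bValues = as.numeric(bValues),
      dHealthy = sort(as.numeric(dHealthy)),
      dTumour = sort(as.numeric(dTumour)),
      s0Range = sort(as.numeric(s0Range)),
      t2wTumourDrop = as.numeric(t2wTumourDrop),
      noiseSigma = as.numeric(noiseSigma),
      tumourFraction = as.numeric(tumourFraction),
      lesionCountProbs = as.numeric(lesionCountProbs),
      seed = as.integer(seed))
}

# Rician noise on a magnitude image: sqrt((S + sigma N1)^2 + (sigma N2)^2)
ricianNoise <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  re <- signal + sigma * rnorm(n)
  im <- sigma * rnorm(n)
  array(sqrt(re^2 + im^2), dim = dim(signal))
}

# logical ellipsoid mask on a voxel grid, axes in voxel units
ellipsoidMask <- function(shape, centre, semiAxes) {
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - centre[a]) / semiAxes[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  d2 <= 1
}

#' Generate one synthetic patient study
#'
#' Builds an ellipsoidal prostate gland with 0--2 ellipsoidal lesions,
#' a noiseless DWI signal following S(b) = S0 * exp(-b * D) with the
#' tumour coefficient inside lesions and the healthy coefficient in the
#' remaining gland, an independently generated T2w volume with a
#' fractional signal drop inside lesions, and Rician noise applied to
#' every channel. S0 and T2w baselines carry a smooth multiplicative
#' bias field so even noiseless studies have spatial structure. The
#' study is a deterministic function of (config seed, patientIndex).
#'
#' @param config a [PhantomConfig-class].
#' @param patientIndex 1-based patient index, at most `nPatients`.
#' @param t2wHighRes if TRUE the T2w volume is super-sampled to a finer
#'   in-plane grid (0.49 mm-style geometry); otherwise it shares the
#'   DWI grid.
#' @return A [PatientStudy-class] with ground-truth parameters attached.
#' @export
generateStudy <- function(config, patientIndex, t2wHighRes = FALSE) {
  stopIfNot(is(config, "PhantomConfig"), "config must be a PhantomConfig")
  stopIfNot(patientIndex >= 1 && patientIndex <= config@nPatients,
            "patientIndex out of range")
  shape <- config@gridShape
  if (any(shape < 8L))
    stop("degenerate grid: every axis needs at least 8 voxels", call. = FALSE)
  set.seed(patientSeed(config@seed, patientIndex))

  sp <- config@voxelSpacing
  # gland: ellipsoid, semi-axes in mm drawn per patient (prostate-sized)
  glandMm <- c(runif(1, 17, 25), runif(1, 17, 25), runif(1, 12, 18))
  glandVox <- glandMm / sp
  centre <- shape / 2 + runif(3, -1.5, 1.5)
  gland <- ellipsoidMask(shape, centre, glandVox)
  glandVol <- sum(gland)

  # lesions: 0-2 ellipsoids, sized to hit the target tumour fraction
  nLesions <- sample.int(3L, 1L, prob = config@lesionCountProbs) - 1L
  tumour <- array(FALSE, dim = shape)
  lesions <- list()
  if (nLesions > 0) {
    targetVox <- config@tumourFraction * glandVol
    split <- runif(nLesions, 0.7, 1.3)
    split <- split / sum(split)
    for (l in seq_len(nLesions)) {
      volVox <- targetVox * split[l]
      # isotropic-in-mm radius from the target volume, mild anisotropy
      rMm <- (3 * volVox * prod(sp) / (4 * pi))^(1 / 3)
      an <- runif(3, 0.8, 1.25)
      semiMm <- rMm * an / prod(an)^(1 / 3)
      semiVox <- pmax(semiMm / sp, 0.8)
      # place the centre well inside the gland
      u <- runif(3, -0.55, 0.55)
      lcentre <- centre + u * glandVox
      les <- ellipsoidMask(shape, lcentre, semiVox) & gland
      tumour <- tumour | les
      lesions[[l]] <- list(centre = lcentre, semiAxesVox = semiVox)
    }
  }

  # per-patient tissue parameters
  dH <- runif(1, config@dHealthy[1], config@dHealthy[2])
  dT <- runif(1, config@dTumour[1], config@dTumour[2])
  s0Base <- runif(1, config@s0Range[1], config@s0Range[2])
  t2wBase <- runif(1, 400, 800)

  bias <- smoothField(shape)
  s0Map <- s0Base * bias
  s0Map[!gland] <- s0Map[!gland] * 0.6
  dMap <- array(0.0022, dim = shape)     # loose background tissue
  dMap[gland] <- dH
  dMap[tumour] <- dT

  volumes <- lapply(config@bValues, function(b) {
    ricianNoise(s0Map * exp(-b * dMap), config@noiseSigma)
  })
  dwi <- new("DwiSeries", bValues = config@bValues, volumes = volumes,
             spacing = sp)

  t2wBias <- smoothField(shape)
  t2wClean <- t2wBase * t2wBias
  t2wClean[!gland] <- t2wClean[!gland] * 0.35
  t2wClean[tumour] <- t2wClean[tumour] * (1 - config@t2wTumourDrop)
  t2wData <- ricianNoise(t2wClean, config@noiseSigma)
  t2wSpacing <- sp
  if (t2wHighRes) {
    f <- round(sp[1] / 0.49)
    hiShape <- c(shape[1] * f, shape[2] * f, shape[3])
    t2wData <- trilinearResize(t2wData, hiShape)
    t2wSpacing <- c(sp[1] / f, sp[2] / f, sp[3])
  }
  t2w <- new("ModalityVolume", name = "T2w", data = t2wData,
             spacing = t2wSpacing)

  gt <- list(
    patientIndex = patientIndex,
    dHealthy = dH, dTumour = dT, s0Base = s0Base, t2wBase = t2wBase,
    glandSemiAxesMm = glandMm, glandCentre = centre,
    nLesions = nLesions, lesions = lesions,
    glandVoxels = glandVol, tumourVoxels = sum(tumour),
    tumourFractionRealized = sum(tumour) / glandVol,
    noiseSigma = config@noiseSigma,
    seedUsed = patientSeed(config@seed, patientIndex)
  )
  new("PatientStudy",
      patientId = sprintf("P%03d", patientIndex),
      dwi = dwi, t2w = t2w,
      glandMask = gland, tumourMask = tumour,
      derived = list(), groundTruth = gt)
}

#' Generate a full synthetic cohort
#'
#' Calls [generateStudy()] for every patient index; per-patient
#' parameters (baseline signal, diffusion coefficients, lesion count
#' and size) vary across patients, and the lesion-count prior allows
#' lesion-free patients. Deterministic given the config seed.
#'
#' @param config a [PhantomConfig-class] with `nPatients >= 2`.
#' @param t2wHighRes passed to [generateStudy()].
#' @return A list of [PatientStudy-class] objects.
#' @export
generateCohort <- function(config, t2wHighRes = FALSE) {
  stopIfNot(config@nPatients >= 2L, "a cohort needs at least 2 patients")
  lapply(seq_len(config@nPatients), function(i)
    generateStudy(config, i, t2wHighRes = t2wHighRes))
}
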
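#' Fit an apparent diffusion coefficient map
#'
#' Per-voxel ordinary least squares of log signal against b under the
#' mono-exponential model S(b) = S0 * exp(-b * D): the slope estimates
#' -D and the intercept log S0. Signals are clamped to a small positive
#' floor before the log; negative fitted D is clamped to 0; voxels
#' outside the mask are set to 0. A masked voxel whose signal is zero
#' at every b-value yields D = 0, S0 = 0 and is counted in the
#' `nDegenerate` attribute of the ADC volume (with a warning).
#'
#' @param series a [DwiSeries-class] with at least 2 distinct b-values.
#' @param mask logical volume on the series grid; only masked voxels
#'   are fitted.
#' @return A list with elements `adc` and `s0`, both
#'   [ModalityVolume-class] objects (names "ADC" and "S0").
#' @examples
#' # exact on noiseless mono-exponential data
#' b <- c(0, 100, 400, 1000)
#' vols <- lapply(b, function(bb) array(1000 * exp(-bb * 0.0018), c(8, 8, 8)))
#' s <- new("DwiSeries", bValues = b, volumes = vols, spacing = c(1.56, 1.56, 3))
#' fit <- fitADC(s, array(TRUE, c(8, 8, 8)))
#' range(imageData(fit$adc))  # 0.0018
#' @export
fitADC <- function(series, mask) {
  stopIfNot(is(series, "DwiSeries"), "series must be a DwiSeries")
  b <- series@bValues
  stopIfNot(length(unique(b)) >= 2L, "need at least 2 distinct b-values")
  d <- dim(series@volumes[[1]])
  stopIfNot(identical(dim(mask), d), "mask must share the series grid")
  idx <- which(mask)
  S <- vapply(series@volumes, function(v) v[idx], numeric(length(idx)))
  if (length(idx) == 1L) S <- matrix(S, nrow = 1L)
  allZero <- rowSums(S > 0) == 0L
  nDegenerate <- sum(allZero)
  if (nDegenerate > 0)
    warning(nDegenerate, " masked voxel(s) with all-zero signal; D = S0 = 0 there")
  eps <- 1e-6
  Y <- log(pmax(S, eps))
  # closed-form OLS of each row of Y on b
  bc <- b - mean(b)
  slope <- as.numeric(Y %*% bc) / sum(bc^2)
  intercept <- rowMeans(Y) - slope * mean(b)
  D <- pmax(-slope, 0)
  S0 <- exp(intercept)
  D[allZero] <- 0
  S0[allZero] <- 0
  adc <- array(0, dim = d); adc[idx] <- D
  s0 <- array(0, dim = d); s0[idx] <- S0
  attr(adc, "nDegenerate") <- nDegenerate
  list(
    adc = new("ModalityVolume", name = "ADC", data = adc,
              spacing = series@spacing),
    s0 = new("ModalityVolume", name = "S0", data = s0,
             spacing = series@spacing)
  )
}

#' Compute a high-b diffusion-weighted image by extrapolation
#'
#' Synthesizes the DWI signal at an unacquired high b-value (default
#' 2000 s/mm^2) as S0(x) * exp(-bTarget * D(x)) from the least-squares
#' ADC/S0 maps. This is strictly an extrapolator: `bTarget` must exceed
#' the largest acquired b-value.
#'
#' @param series a [DwiSeries-class].
#' @param mask logical volume; the fit (and output) is restricted to it.
#' @param bTarget target b-value in s/mm^2, greater than `max(bValues)`.
#' @param fit optional precomputed [fitADC()] result to reuse.
#' @return A [ModalityVolume-class] named "CHB-DWI".
#' @export
computeCHBDWI <- function(series, mask, bTarget = 2000, fit = NULL) {
  stopIfNot(is(series, "DwiSeries"), "series must be a DwiSeries")
  if (bTarget <= max(series@bValues))
    stop("bTarget (", bTarget, ") must exceed the largest acquired b-value (",
         max(series@bValues), ")", call. = FALSE)
  if (is.null(fit)) fit <- fitADC(series, mask)
  out <- fit$s0@data * exp(-bTarget * fit$adc@data)
  out[!mask] <- 0
  new("ModalityVolume", name = "CHB-DWI", data = out,
      spacing = series@spacing)
}

#' Compute a correlated diffusion image
#'
#' Mixes the signal across all acquired b-values inside a local
#' subvolume: at voxel x, the cross-b product prod_i S_i(y) is averaged
#' over all voxels y of the box subvolume around x (clipped at image
#' borders). With the empirical (delta-mass) estimator of the
#' conditional joint signal density this is the discretization of the
#' signal-mixing integral. Tumour tissue, whose signal decays slowly
#' with b, retains large products and appears bright.
#'
#' @param series a [DwiSeries-class] of co-registered volumes.
#' @param mask logical volume; used for the optional rescaling and to
#'   zero the output outside the gland.
#' @param subvolumeRadius box radius in voxels per axis (length 1 or 3);
#'   the default `c(1, 1, 0)` is a 3 x 3 in-plane subvolume (slices are
#'   thick, so no through-plane mixing).
#' @param rescale if TRUE (default), min-max rescale the in-mask values
#'   to `[0, 1]` over the mask; raw cross-b products are otherwise of
#'   order S0^(number of b-values).
#' @return A [ModalityVolume-class] named "CDI".
#' @export
computeCDI <- function(series, mask, subvolumeRadius = c(1, 1, 0),
                       rescale = TRUE) {
  stopIfNot(is(series, "DwiSeries"), "series must be a DwiSeries")
  radius <- rep_len(as.integer(subvolumeRadius), 3L)
  stopIfNot(all(radius >= 0L), "subvolumeRadius must be >= 0")
  d <- dim(series@volumes[[1]])
  stopIfNot(identical(dim(mask), d), "mask must share the series grid")
  prodVol <- Reduce(`*`, series@volumes)
  cdi <- if (all(radius == 0L)) prodVol else boxMean3D(prodVol, radius)
  if (any(!is.finite(cdi)))
    stop("empty or degenerate subvolume encountered", call. = FALSE)
  if (rescale) {
    v <- cdi[mask]
    rng <- range(v)
    cdi <- if (diff(rng) > 0) (cdi - rng[1]) / diff(rng) else cdi * 0
    cdi[cdi < 0] <- 0; cdi[cdi > 1] <- 1
  }
  cdi[!mask] <- 0
  new("ModalityVolume", name = "CDI", data = cdi, spacing = series@spacing)
}

#' Attach all derived modalities to a study
#'
#' Computes ADC, CHB-DWI and CDI from the study's DWI series (restricted
#' to the gland mask) and registers them, together with the individual
#' b-value images b1..b4, in the study's `derived` list.
#'
#' @param study a [PatientStudy-class].
#' @param bTarget CHB-DWI extrapolation b-value (s/mm^2).
#' @param cdiRadius CDI subvolume radius, see [computeCDI()].
#' @return The study with its `derived` slot filled.
#' @export
deriveModalities <- function(study, bTarget = 2000, cdiRadius = c(1, 1, 0)) {
  stopIfNot(is(study, "PatientStudy"), "study must be a PatientStudy")
  mask <- study@glandMask
  fit <- fitADC(study@dwi, mask)
  chb <- computeCHBDWI(study@dwi, mask, bTarget = bTarget, fit = fit)
  cdi <- computeCDI(study@dwi, mask, subvolumeRadius = cdiRadius)
  derived <- list(ADC = fit$adc, "CHB-DWI" = chb, CDI = cdi, S0 = fit$s0)
  for (i in seq_along(study@dwi@bValues)) {
    derived[[paste0("b", i)]] <- new("ModalityVolume",
      name = paste0("b", i), data = study@dwi@volumes[[i]],
      spacing = study@dwi@spacing)
  }
  study@derived <- derived
  study
}

#' Fetch any modality volume of a study by name
#'
#' @param study a [PatientStudy-class] (after [deriveModalities()] for
#'   derived names).
#' @param name one of T2w, ADC, CHB-DWI, CDI, b1..b4 (or S0).
#' @return The matching [ModalityVolume-class].
#' @export
studyModality <- function(study, name) {
  if (name == "T2w") return(study@t2w)
  if (name %in% names(study@derived)) return(study@derived[[name]])
  stop("modality '", name, "' not present on study ", study@patientId,
       " (run deriveModalities()?)", call. = FALSE)
}
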
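GLCM_STAT_NAMES <- c(
  "energy", "contrast", "correlation", "variance",
  "inverse_difference_moment", "sum_average", "sum_variance",
  "sum_entropy", "entropy", "difference_variance", "difference_entropy",
  "imc1", "homogeneity", "autocorrelation", "dissimilarity",
  "cluster_shade", "cluster_prominence", "maximum_probability")

GLCM_DIRECTIONS <- c(0, 45, 90, 135)
GABOR_FREQUENCIES <- c(0.1, 0.25, 0.4)
GABOR_ORIENTATIONS <- c(0, 45, 90, 135)
KIRSCH_DIRECTIONS <- c("N", "NW", "W", "SW", "S", "SE", "E", "NE")

#' First-order statistical features of a window
#'
#' Mean, population standard deviation, skewness and excess kurtosis of
#' the grey-level intensities. For a constant window, skewness and
#' kurtosis are defined as 0.
#'
#' @param window numeric vector or matrix of pixel intensities.
#' @return Named numeric vector of length 4.
#' @examples
#' firstOrderFeatures(1:9)  # mean 5, population sd ~2.582
#' @export
firstOrderFeatures <- function(window) {
  x <- as.numeric(window)
  stopIfNot(length(x) > 0, "window must be non-empty")
  m1 <- mean(x)
  d <- x - m1
  m2 <- mean(d^2)
  if (m2 > 1e-24) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  c(mean = m1, std = sqrt(m2), skewness = skew, kurtosis = kurt)
}

# map a window to integer grey levels 1..L. Integer-valued input is
# treated as already-quantized (shifted to 1-based); continuous input is
# min-max binned into L levels.
quantizePatch <- function(patch, levels) {
  x <- as.matrix(patch)
  if (all(x == round(x))) {
    q <- x - min(x) + 1
    if (max(q) > levels)
      stop("integer patch has more than `levels` grey levels", call. = FALSE)
    return(matrix(as.integer(q), nrow(x), ncol(x)))
  }
  quantizeMinMax(x, range(x), levels)
}

# min-max quantization of arbitrary data against a fixed range
quantizeMinMax <- function(data, rng, levels) {
  if (diff(rng) <= 0) {
    q <- array(1L, dim = dim(data))
  } else {
    q <- floor((data - rng[1]) / diff(rng) * levels) + 1
    q[q < 1] <- 1; q[q > levels] <- levels
    storage.mode(q) <- "integer"
  }
  q
}

#' Grey-level co-occurrence (Haralick) features of a window
#'
#' Builds the symmetric, normalized GLCM at offset distance 1 for each
#' requested direction and computes 18 statistics per direction:
#' energy, contrast, correlation, variance, inverse difference moment,
#' sum average, sum variance, sum entropy, entropy, difference
#' variance, difference entropy, information measure of correlation
#' (variant IMC1), homogeneity, autocorrelation, dissimilarity, cluster
#' shade, cluster prominence and maximum probability. Entropies are in
#' bits. For a constant window: energy 1, contrast 0, and the
#' entropy/correlation-type features 0.
#'
#' Integer-valued patches are treated as already quantized; continuous
#' patches are min-max quantized to `levels` grey levels.
#'
#' @param patch numeric matrix (the window).
#' @param levels number of grey levels.
#' @param directions GLCM directions in degrees, a subset of
#'   c(0, 45, 90, 135).
#' @return Named numeric vector, 18 values per direction.
#' @examples
#' glcmFeatures(matrix(c(0, 1, 1, 0), 2), directions = 0)["contrast/d0"]
#' @export
glcmFeatures <- function(patch, levels = 16L,
                         directions = GLCM_DIRECTIONS) {
  stopIfNot(all(directions %in% GLCM_DIRECTIONS),
            "directions must be among 0, 45, 90, 135")
  q <- quantizePatch(patch, levels)
  L <- max(levels, max(q))
  out <- unlist(lapply(directions, function(ang) {
    v <- cppGlcmStats(q, L, match(ang, GLCM_DIRECTIONS) - 1L)
    names(v) <- paste0(GLCM_STAT_NAMES, "/d", ang)
    v
  }))
  out
}

#' Gabor filter kernel
#'
#' Complex Gabor kernel at the given spatial frequency (cycles/pixel)
#' and orientation (degrees from the x axis). The Gaussian envelope
#' scale defaults to 0.56 / frequency (about one octave bandwidth).
#'
#' @param frequency cycles per pixel.
#' @param theta orientation in degrees.
#' @param sigma Gaussian envelope standard deviation in pixels.
#' @param gamma spatial aspect ratio of the envelope.
#' @return A complex matrix of odd size.
#' @export
gaborKernel <- function(frequency, theta, sigma = 0.56 / frequency,
                        gamma = 1) {
  h <- max(3L, ceiling(2.5 * sigma))
  g <- expand.grid(y = -h:h, x = -h:h)  # rows = y, cols = x
  th <- theta * pi / 180
  xr <- g$x * cos(th) + g$y * sin(th)
  yr <- -g$x * sin(th) + g$y * cos(th)
  k <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2)) *
    exp(2i * pi * frequency * xr)
  matrix(k, 2L * h + 1L, 2L * h + 1L)
}

#' Gabor filter-bank magnitude responses of a 2-D image
#'
#' Filters the whole image (FFT convolution, zero padding) with one
#' complex Gabor kernel per (frequency, orientation) pair and returns
#' the response magnitudes. Image-level filtering avoids window-edge
#' artefacts; per-window features are obtained by pooling afterwards.
#'
#' @param image numeric matrix.
#' @param frequencies spatial frequencies in cycles/pixel.
#' @param orientations orientations in degrees.
#' @return Named list of magnitude matrices ("f<freq>/o<angle>").
#' @export
gaborResponses <- function(image, frequencies = GABOR_FREQUENCIES,
                           orientations = GABOR_ORIENTATIONS) {
  out <- list()
  for (f in frequencies) for (o in orientations) {
    k <- gaborKernel(f, o)
    out[[paste0("f", f, "/o", o)]] <- Mod(conv2sameComplex(image, k))
  }
  out
}

#' Gabor features of an image region
#'
#' One value per (scale, orientation): the mean Gabor response
#' magnitude over the image (12 values with the default 3 frequencies
#' and 4 orientations).
#'
#' @inheritParams gaborResponses
#' @return Named numeric vector of mean magnitudes.
#' @export
gaborFeatures <- function(image, frequencies = GABOR_FREQUENCIES,
                          orientations = GABOR_ORIENTATIONS) {
  resp <- gaborResponses(image, frequencies, orientations)
  vapply(resp, mean, numeric(1))
}

#' The eight Kirsch compass kernels
#'
#' Classic 3 x 3 masks with weights +5 on three consecutive compass
#' positions and -3 elsewhere; all kernels sum to zero, so responses
#' are invariant to adding a constant to the image.
#'
#' @return Named list of eight 3 x 3 matrices (N, NW, W, SW, S, SE, E, NE).
#' @export
kirschKernels <- function() {
  # ring of the 8 positions around the centre, clockwise from top-left
  ring <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3), c(3, 3), c(3, 2),
                c(3, 1), c(2, 1))
  out <- list()
  for (k in 0:7) {
    m <- matrix(0, 3, 3)
    w <- c(5, 5, 5, -3, -3, -3, -3, -3)[((seq_len(8) - 1 + k) %% 8) + 1]
    m[ring] <- w
    out[[KIRSCH_DIRECTIONS[k + 1]]] <- m
  }
  out
}

#' Kirsch compass gradient responses of a 2-D image
#'
#' Applies the eight Kirsch kernels (replicate border handling) and
#' returns the signed response images.
#'
#' @param image numeric matrix, at least 3 x 3.
#' @return Named list of eight response matrices.
#' @export
kirschResponses <- function(image) {
  stopIfNot(nrow(image) >= 3 && ncol(image) >= 3,
            "image must be at least 3 x 3")
  lapply(kirschKernels(), function(k) conv3x3Replicate(image, k))
}

#' Kirsch features of an image region
#'
#' Feature k is the maximum absolute response of compass kernel k over
#' the region: the maximum gradient in each of eight directions.
#'
#' @param image numeric matrix, at least 3 x 3.
#' @return Named numeric vector of length 8.
#' @export
kirschFeatures <- function(image) {
  vapply(kirschResponses(image), function(r) max(abs(r)), numeric(1))
}

featureNamesForModality <- function(modality,
                                    frequencies = GABOR_FREQUENCIES,
                                    orientations = GABOR_ORIENTATIONS) {
  c(paste0(modality, "/firstorder/",
           c("mean", "std", "skewness", "kurtosis")),
    unlist(lapply(GLCM_DIRECTIONS, function(ang)
      paste0(modality, "/glcm/", GLCM_STAT_NAMES, "/d", ang))),
    unlist(lapply(frequencies, function(f)
      paste0(modality, "/gabor/f", f, "/o", orientations))),
    paste0(modality, "/kirsch/", KIRSCH_DIRECTIONS))
}
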
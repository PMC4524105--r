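# equal-width discretization of a numeric vector into 1..bins
discretizeColumn <- function(x, bins) {
  if (!is.numeric(x)) x <- as.numeric(as.factor(x))
  quantizeMinMax(matrix(x), range(x), bins)[, 1]
}

miFromCodes <- function(xi, yi, nx, ny) {
  joint <- tabulate(xi + nx * (yi - 1L), nbins = nx * ny)
  n <- length(xi)
  p <- joint[joint > 0] / n
  px <- tabulate(xi, nbins = nx) / n
  py <- tabulate(yi, nbins = ny) / n
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy <- -sum(p * log2(p))
  max(hx + hy - hxy, 0)
}

#' Mutual information between two sample vectors
#'
#' Plug-in mutual information in bits from the joint histogram after
#' equal-width discretization of continuous inputs into `bins` bins.
#' Factor or integer-coded class vectors are used as-is. A constant
#' column has zero mutual information with any target.
#'
#' @param x,y equal-length sample vectors (numeric or factor).
#' @param bins number of equal-width bins for continuous columns.
#' @return Non-negative mutual information in bits.
#' @examples
#' x <- rep(0:1, each = 500)
#' mutualInformation(x, x)  # 1 bit
#' @export
mutualInformation <- function(x, y, bins = 16L) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(bins >= 2, "bins must be >= 2")
  xi <- discretizeColumn(x, bins)
  yi <- discretizeColumn(y, bins)
  miFromCodes(xi, yi, max(xi), max(yi))
}

#' Greedy maximum-relevance minimum-redundancy feature ranking
#'
#' Ranks features by the difference (MID) combination of relevance and
#' redundancy: the first feature maximizes MI(f; class); each
#' subsequent feature maximizes MI(f; class) minus the mean MI(f; g)
#' over the already-selected set. Mutual information is the
#' histogram plug-in estimator of [mutualInformation()]. Ties are
#' broken by lexicographic feature name, so the ranking is
#' deterministic.
#'
#' @param fm a [TextureFeatureMatrix-class] with binary labels, or a
#'   numeric matrix (then `labels` must be given).
#' @param maxM how many features to rank (default all).
#' @param bins discretization bins for the MI estimator.
#' @param labels optional label vector when `fm` is a plain matrix.
#' @return Character vector of ranked feature names, length `maxM`.
#' @export
mrmrRank <- function(fm, maxM = NULL, bins = 16L, labels = NULL) {
  if (is(fm, "TextureFeatureMatrix")) {
    values <- fm@values
    labels <- fm@labels
  } else {
    values <- fm
    stopIfNot(!is.null(labels), "labels required for a plain matrix")
  }
  stopIfNot(length(unique(as.character(labels))) == 2L,
            "mRMR ranking requires binary labels")
  p <- ncol(values)
  if (is.null(maxM)) maxM <- p
  stopIfNot(maxM >= 1 && maxM <= p, "maxM must be within 1..feature count")
  fn <- colnames(values)

  codes <- apply(values, 2, discretizeColumn, bins = bins)
  nlev <- apply(codes, 2, max)
  ci <- discretizeColumn(labels, bins)
  nc <- max(ci)

  relevance <- vapply(seq_len(p), function(j)
    miFromCodes(codes[, j], ci, nlev[j], nc), numeric(1))

  selected <- integer(0)
  available <- seq_len(p)
  redundancySum <- numeric(p)
  for (step in seq_len(maxM)) {
    score <- relevance[available]
    if (length(selected))
      score <- score - redundancySum[available] / length(selected)
    best <- available[order(-score, fn[available])][1]
    selected <- c(selected, best)
    available <- setdiff(available, best)
    if (length(available) && step < maxM) {
      add <- vapply(available, function(j)
        miFromCodes(codes[, j], codes[, best], nlev[j], nlev[best]),
        numeric(1))
      redundancySum[available] <- redundancySum[available] + add
    }
  }
  fn[selected]
}

#' Criterion-driven choice of the mRMR subset size
#'
#' Sweeps subset sizes m over `mGrid`: for each m, the first m features
#' of the mRMR ranking are scored with a patient-grouped
#' cross-validated SVM evaluator, and the m maximizing the requested
#' criterion is selected (ties broken towards the smallest m). The full
#' score curve is returned alongside the choice.
#'
#' @param fm a [TextureFeatureMatrix-class].
#' @param criterion one of "sensitivity", "specificity", "auc".
#' @param mGrid candidate subset sizes; default 10, 20, ... up to the
#'   feature count.
#' @param evaluator scoring function `(fm, subset, seed)` returning a
#'   named metric vector containing at least the criterion; defaults to
#'   the package's grouped-CV SVM scorer [cvScore()].
#' @param ranked optional precomputed mRMR ranking to reuse.
#' @param seed RNG seed forwarded to the evaluator.
#' @param scoreTol scores within `scoreTol` of the maximum count as
#'   tied, and the smallest tied m wins (a one-standard-error-style
#'   parsimony rule: cross-validated scores carry noise of about this
#'   size, so exact ties essentially never occur).
#' @param ... further arguments passed to [cvScore()].
#' @return A [SelectionResult-class].
#' @export
selectBestM <- function(fm, criterion = c("auc", "sensitivity", "specificity"),
                        mGrid = NULL, evaluator = NULL, ranked = NULL,
                        seed = 1L, scoreTol = 0.01, ...) {
  criterion <- match.arg(criterion)
  p <- ncol(fm@values)
  if (is.null(mGrid)) mGrid <- unique(c(seq(10L, p, by = 10L), p))
  mGrid <- sort(unique(pmin(as.integer(mGrid), p)))
  stopIfNot(all(mGrid >= 1), "mGrid must contain sizes >= 1")
  if (is.null(ranked)) ranked <- mrmrRank(fm, maxM = max(mGrid))
  if (is.null(evaluator))
    evaluator <- function(fm, subset, seed) {
      cvScore(fm, subset, thresholdPolicy = criterion, seed = seed, ...)
    }
  rows <- lapply(mGrid, function(m) {
    metrics <- tryCatch(evaluator(fm, ranked[seq_len(m)], seed),
                        error = function(e)
                          stop("evaluator failed at m = ", m, ": ",
                               conditionMessage(e), call. = FALSE))
    c(m = m, metrics)
  })
  curve <- as.data.frame(do.call(rbind, rows))
  score <- curve[[criterion]]
  tied <- score >= max(score) - scoreTol
  bestM <- as.integer(min(curve$m[tied]))
  curve$score <- score
  new("SelectionResult",
      criterion = criterion,
      rankedFeatures = ranked,
      bestM = bestM,
      bestSubset = ranked[seq_len(bestM)],
      scoreCurve = curve)
}
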
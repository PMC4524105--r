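#' Leave-one-patient-out fold assignments
#'
#' One fold per distinct patient id: the test fold is that patient's
#' samples, the training set everyone else's. Every sample appears in
#' exactly one test fold.
#'
#' @param fm a [TextureFeatureMatrix-class] with at least 2 patients.
#' @return Named list (patient id -> integer sample indices).
#' @export
lopoFolds <- function(fm) {
  ids <- fm@patientIds
  u <- sort(unique(ids))
  stopIfNot(length(u) >= 2L, "leave-one-patient-out needs >= 2 patients")
  lapply(setNames(u, u), function(p) which(ids == p))
}

# deterministic assignment of patients to k groups (round-robin on the
# sorted ids) for the grouped CV used during feature selection
patientGroups <- function(ids, k) {
  u <- sort(unique(ids))
  k <- min(k, length(u))
  grp <- setNames(rep(seq_len(k), length.out = length(u)), u)
  split(seq_along(ids), grp[ids])
}

#' Choose an operating threshold on training decision scores
#'
#' `"youden"` maximizes sensitivity + specificity - 1. The
#' criterion-specific policies maximize the prioritized rate subject to
#' the complementary rate staying at or above `floor` (falling back to
#' Youden's J when no threshold satisfies the floor), reflecting
#' clinical scenarios where one error type dominates (screening favours
#' sensitivity, surgical planning favours specificity).
#'
#' @param scores decision scores (larger = more cancer-like).
#' @param labels factor with levels healthy/cancer.
#' @param policy "youden", "sensitivity" or "specificity".
#' @param floor minimum acceptable complementary rate.
#' @return A threshold value; samples with score >= threshold are
#'   called cancerous.
#' @export
chooseThreshold <- function(scores, labels,
                            policy = c("youden", "sensitivity", "specificity"),
                            floor = 0.6) {
  policy <- match.arg(policy)
  pos <- labels == "cancer"
  stopIfNot(any(pos) && any(!pos), "both classes needed to set a threshold")
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  sens <- tp / sum(pos)
  spec <- 1 - fp / sum(!pos)
  # candidate thresholds: midpoints between consecutive distinct scores,
  # so the operating point sits in the centre of the decision gap and
  # transfers better to held-out patients
  s <- scores[ord]
  cand <- which(c(s[-length(s)] != s[-1], TRUE))  # last index per distinct score
  nextScore <- c(s[cand[-1]], s[length(s)] - 1)
  thr <- (s[cand] + nextScore) / 2
  sens <- sens[cand]; spec <- spec[cand]
  pick <- switch(policy,
    youden = which.max(sens + spec - 1),
    sensitivity = {
      ok <- spec >= floor
      if (any(ok)) which(ok)[which.max(sens[ok])] else which.max(sens + spec - 1)
    },
    specificity = {
      ok <- sens >= floor
      if (any(ok)) which(ok)[which.max(spec[ok])] else which.max(sens + spec - 1)
    })
  thr[pick]
}

#' Train the window classifier (standardized RBF SVM)
#'
#' Standardizes the selected features with training-fold statistics
#' only, then fits an RBF support vector machine with class weights
#' inversely proportional to class frequency (the cancerous class is a
#' small minority; unweighted training would collapse to the majority
#' class). Decision scores are oriented so that larger means more
#' cancer-like, and an operating threshold is chosen on the training
#' scores by [chooseThreshold()].
#'
#' @param fm training [TextureFeatureMatrix-class] containing both
#'   classes.
#' @param features feature names to use.
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses the
#'   library default 1/(number of features).
#' @param thresholdPolicy passed to [chooseThreshold()] ("auc" is an
#'   alias for "youden").
#' @return A [WindowClassifier-class].
#' @export
trainClassifier <- function(fm, features = featureNames(fm), cost = 1,
                            gamma = NULL, thresholdPolicy = "youden") {
  if (thresholdPolicy == "auc") thresholdPolicy <- "youden"
  x <- fm@values[, features, drop = FALSE]
  y <- droplevels(fm@labels)
  if (nlevels(y) < 2L)
    stop("training fold contains a single class; cannot train", call. = FALSE)
  centre <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  xs <- scale(x, center = centre, scale = scl)
  w <- length(y) / (2 * table(y))
  if (is.null(gamma)) gamma <- 1 / ncol(xs)
  fit <- e1071::svm(xs, y, kernel = "radial", cost = cost, gamma = gamma,
                    class.weights = w, scale = FALSE)
  dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
             "decision.values")
  flip <- if (grepl("^cancer", colnames(dv)[1])) 1 else -1
  scores <- flip * dv[, 1]
  thr <- chooseThreshold(scores, y, policy = thresholdPolicy)
  new("WindowClassifier", fit = fit, features = features,
      centre = centre, scale = scl, threshold = thr, flip = flip)
}

#' Decision scores of a trained classifier on new samples
#'
#' Applies the classifier's stored (training-fold) standardization and
#' returns continuous decision scores, larger = more cancer-like.
#'
#' @param clf a [WindowClassifier-class].
#' @param fm a [TextureFeatureMatrix-class] (or plain numeric matrix
#'   with matching column names).
#' @return Numeric score vector.
#' @export
decisionScores <- function(clf, fm) {
  x <- if (is(fm, "TextureFeatureMatrix")) fm@values else fm
  x <- x[, clf@features, drop = FALSE]
  xs <- scale(x, center = clf@centre, scale = clf@scale)
  dv <- attr(stats::predict(clf@fit, xs, decision.values = TRUE),
             "decision.values")
  clf@flip * dv[, 1]
}

#' Sensitivity, specificity and accuracy at a threshold
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/n, for the rule "cancer iff score >= threshold". A rate
#' whose denominator is empty (no positives, or no negatives) is
#' reported as NA rather than 0.
#'
#' @param scores per-sample decision values.
#' @param labels factor with levels healthy/cancer (or logical, TRUE =
#'   cancer).
#' @param threshold operating threshold.
#' @return Named vector: sensitivity, specificity, accuracy, tp, fn,
#'   tn, fp.
#' @export
scoreMetrics <- function(scores, labels, threshold) {
  stopIfNot(length(scores) == length(labels),
            "scores and labels must have equal length")
  pos <- if (is.logical(labels)) labels else labels == "cancer"
  call <- scores >= threshold
  tp <- sum(call & pos); fn <- sum(!call & pos)
  tn <- sum(!call & !pos); fp <- sum(call & !pos)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(scores),
    tp = tp, fn = fn, tn = tn, fp = fp)
}

#' ROC curve and AUC by trapezoidal integration
#'
#' Sweeps all score thresholds, returning the ordered (FPR, TPR) points
#' from (0,0) to (1,1) and the trapezoid area under them. Tied scores
#' contribute half, so the AUC equals the Mann-Whitney rank statistic
#' U / (n+ * n-).
#'
#' @param scores per-sample decision values.
#' @param labels factor with levels healthy/cancer (or logical).
#' @return List with `auc` and `roc` (data.frame fpr, tpr).
#' @export
rocAuc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "cancer"
  nP <- sum(pos); nN <- sum(!pos)
  stopIfNot(nP > 0 && nN > 0, "ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  p <- pos[ord]; s <- scores[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- c(s[-length(s)] != s[-1], TRUE)  # collapse tied thresholds
  tpr <- c(0, tp[last] / nP)
  fpr <- c(0, fp[last] / nN)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Percentile-bootstrap confidence interval over patients
#'
#' Resamples patients with replacement, recomputes the pooled metric
#' from the resampled patients' samples, and reports the 2.5/97.5
#' percentiles. If the metric is undefined (NA) in more than half of
#' the resamples, the interval is reported as NA.
#'
#' @param patientIds per-sample patient ids.
#' @param metricFun function(sampleIndex) -> scalar metric for a pooled
#'   set of samples.
#' @param reps bootstrap replicates.
#' @param seed RNG seed.
#' @return Numeric length-2 vector (lower, upper).
#' @export
bootstrapCI <- function(patientIds, metricFun, reps = 2000L, seed = 1L) {
  u <- unique(patientIds)
  stopIfNot(length(u) >= 2L, "bootstrap needs >= 2 patients")
  byPatient <- lapply(setNames(u, u), function(p) which(patientIds == p))
  set.seed(seed)
  vals <- vapply(seq_len(reps), function(r) {
    pick <- sample(u, length(u), replace = TRUE)
    metricFun(unlist(byPatient[pick], use.names = FALSE))
  }, numeric(1))
  if (mean(is.na(vals)) > 0.5) return(c(NA_real_, NA_real_))
  unname(quantile(vals, c(0.025, 0.975), na.rm = TRUE))
}

# grouped-CV SVM scorer used during feature selection: k patient groups,
# per-fold training (with a cap on healthy samples for tractability),
# pooled held-out metrics at per-fold training thresholds
cvScore <- function(fm, subset, nGroups = 4L, cost = 1, gamma = NULL,
                    maxTrainNeg = 3000L, thresholdPolicy = "youden",
                    seed = 1L) {
  folds <- patientGroups(fm@patientIds, nGroups)
  scores <- numeric(0); labels <- character(0)
  counts <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  for (k in seq_along(folds)) {
    testIdx <- folds[[k]]
    trainIdx <- setdiff(seq_along(fm@patientIds), testIdx)
    trainIdx <- capNegatives(fm, trainIdx, maxTrainNeg,
                             seed = seed + 131L * k)
    train <- subsetFeatures(fm, subset, trainIdx)
    test <- subsetFeatures(fm, subset, testIdx)
    clf <- trainClassifier(train, subset, cost = cost, gamma = gamma,
                           thresholdPolicy = thresholdPolicy)
    sc <- decisionScores(clf, test)
    m <- scoreMetrics(sc, test@labels, clf@threshold)
    counts <- counts + m[c("tp", "fn", "tn", "fp")]
    scores <- c(scores, sc)
    labels <- c(labels, as.character(test@labels))
  }
  auc <- rocAuc(scores, factor(labels, levels = c("healthy", "cancer")))$auc
  c(sensitivity = unname(counts["tp"] / (counts["tp"] + counts["fn"])),
    specificity = unname(counts["tn"] / (counts["tn"] + counts["fp"])),
    accuracy = unname((counts["tp"] + counts["tn"]) / sum(counts)),
    auc = auc)
}

# subsample the healthy class of a training index set to at most maxNeg
# samples (all cancerous samples are kept); deterministic given seed
capNegatives <- function(fm, trainIdx, maxNeg, seed) {
  neg <- trainIdx[fm@labels[trainIdx] == "healthy"]
  pos <- setdiff(trainIdx, neg)
  if (length(neg) > maxNeg) {
    set.seed(seed)
    neg <- sort(sample(neg, maxNeg))
  }
  sort(c(pos, neg))
}

#' Leave-one-patient-out evaluation of a feature subset
#'
#' For each patient: train the classifier on all other patients
#' (healthy samples capped for tractability), score the held-out
#' patient, and record the per-patient confusion at the training-fold
#' operating threshold. Pooled sensitivity, specificity and accuracy
#' come from the summed confusion counts; pooled AUC from all held-out
#' scores; 95% confidence intervals from a patient-level percentile
#' bootstrap.
#'
#' @param fm a [TextureFeatureMatrix-class].
#' @param features feature subset to evaluate.
#' @param cost,gamma SVM hyperparameters.
#' @param maxTrainNeg cap on healthy training samples per fold.
#' @param thresholdPolicy operating-threshold policy, see
#'   [chooseThreshold()].
#' @param bootReps patient-bootstrap replicates for the CIs.
#' @param seed RNG seed (training subsampling and bootstrap).
#' @return An [EvaluationReport-class].
#' @export
evaluateSubset <- function(fm, features, cost = 1, gamma = NULL,
                           maxTrainNeg = 3000L, thresholdPolicy = "youden",
                           bootReps = 2000L, seed = 1L) {
  folds <- lopoFolds(fm)
  n <- length(fm@patientIds)
  scores <- numeric(n); calls <- logical(n)
  perPatient <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    testIdx <- folds[[k]]
    trainIdx <- capNegatives(fm, setdiff(seq_len(n), testIdx), maxTrainNeg,
                             seed = seed + 977L * k)
    clf <- trainClassifier(subsetFeatures(fm, features, trainIdx), features,
                           cost = cost, gamma = gamma,
                           thresholdPolicy = thresholdPolicy)
    sc <- decisionScores(clf, subsetFeatures(fm, features, testIdx))
    scores[testIdx] <- sc
    calls[testIdx] <- sc >= clf@threshold
    lab <- fm@labels[testIdx]
    m <- scoreMetrics(sc, lab, clf@threshold)
    pauc <- if (length(unique(lab)) == 2L) rocAuc(sc, lab)$auc else NA_real_
    perPatient[[k]] <- data.frame(
      patient = names(folds)[k], t(m), auc = pauc, n = length(testIdx))
  }
  perPatient <- do.call(rbind, perPatient)
  labels <- fm@labels
  pooledCounts <- colSums(perPatient[, c("tp", "fn", "tn", "fp")])
  roc <- rocAuc(scores, labels)

  pooledMetric <- function(idx, what) {
    lab <- labels[idx]; sc <- scores[idx]; cl <- calls[idx]
    pos <- lab == "cancer"
    switch(what,
      sensitivity = if (any(pos)) sum(cl & pos) / sum(pos) else NA_real_,
      specificity = if (any(!pos)) sum(!cl & !pos) / sum(!pos) else NA_real_,
      accuracy = mean(cl == pos),
      auc = if (length(unique(lab)) == 2L) rocAuc(sc, lab)$auc else NA_real_)
  }
  pooled <- list()
  all <- seq_len(n)
  for (w in c("sensitivity", "specificity", "accuracy", "auc")) {
    ci <- bootstrapCI(fm@patientIds,
                      function(idx) pooledMetric(idx, w),
                      reps = bootReps, seed = seed + match(w, c(
                        "sensitivity", "specificity", "accuracy", "auc")))
    pooled[[w]] <- list(estimate = pooledMetric(all, w), ci = ci)
  }
  new("EvaluationReport",
      perPatient = perPatient,
      pooled = pooled,
      roc = roc$roc,
      scores = scores,
      labels = labels,
      patientIds = fm@patientIds,
      nSamples = as.integer(n),
      nCancerous = as.integer(sum(labels == "cancer")),
      config = list(features = features, cost = cost, gamma = gamma,
                    maxTrainNeg = maxTrainNeg,
                    thresholdPolicy = thresholdPolicy,
                    bootReps = bootReps, seed = seed))
}

#' Leave-one-patient-out evaluation of a texture feature model
#'
#' Convenience wrapper: evaluates the model's final feature subset with
#' [evaluateSubset()] using the model's threshold policy.
#'
#' @param model a [TextureFeatureModel-class].
#' @param fm the cohort [TextureFeatureMatrix-class].
#' @param ... passed to [evaluateSubset()].
#' @return An [EvaluationReport-class].
#' @export
evaluateModel <- function(model, fm, ...) {
  policy <- if (model@criterion %in% c("sensitivity", "specificity"))
    model@criterion else "youden"
  evaluateSubset(fm, model@finalSubset, thresholdPolicy = policy, ...)
}
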
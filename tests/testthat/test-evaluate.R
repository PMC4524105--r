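test_that("LOPO folds partition the samples with no patient leakage", {
  fm <- syntheticTable(n = 210, nPatients = 3, seed = 3)
  # force unequal fold sizes 5/7/9-style by patient id assignment
  ids <- c(rep("A", 50), rep("B", 70), rep("C", 90))
  fm@patientIds <- ids
  folds <- lopoFolds(fm)
  expect_length(folds, 3)
  expect_equal(sort(unname(unlist(folds))), seq_len(210))  # partition
  expect_equal(vapply(folds, length, 1L), c(A = 50L, B = 70L, C = 90L))
  for (p in names(folds)) {
    expect_true(all(ids[folds[[p]]] == p))      # test fold = that patient
    expect_false(p %in% ids[-folds[[p]]])       # no leakage into training
  }
  one <- fm; one@patientIds <- rep("A", 210)
  expect_error(lopoFolds(one), ">= 2 patients")
})

test_that("classifier standardization uses training statistics only and is scale-invariant", {
  fm <- syntheticTable(n = 400, nPatients = 8, seed = 5)
  clf <- trainClassifier(fm)
  x <- featureValues(fm)
  expect_equal(clf@centre, colMeans(x), tolerance = 1e-12)
  expect_equal(clf@scale, apply(x, 2, sd), tolerance = 1e-12)
  # test-fold data never changes the stored standardization or other
  # samples' scores
  test1 <- fm; test1@values[1, ] <- test1@values[1, ] + 1e6
  s0 <- decisionScores(clf, fm)
  s1 <- decisionScores(clf, test1)
  expect_equal(s1[-1], s0[-1], tolerance = 1e-9)
  # rescaling a feature column (train+test consistently) leaves the
  # standardized pipeline's scores unchanged
  fmScaled <- fm; fmScaled@values[, 1] <- fmScaled@values[, 1] * 10
  clf2 <- trainClassifier(fmScaled)
  expect_equal(decisionScores(clf2, fmScaled), s0, tolerance = 1e-6)
  # duplicating every column with the default gamma = 1/d halves gamma
  # while doubling squared distances: identical kernel, identical scores
  dupVals <- cbind(featureValues(fm),
                   `dup` = featureValues(fm))
  colnames(dupVals) <- c(featureNames(fm), paste0(featureNames(fm), "#2"))
  fmDup <- fm; fmDup@values <- dupVals
  clf3 <- trainClassifier(fmDup)
  expect_equal(decisionScores(clf3, fmDup), s0, tolerance = 1e-6)
  # single-class folds are rejected
  oneClass <- subsetFeatures(fm, samples = which(sampleLabels(fm) == "healthy"))
  expect_error(trainClassifier(oneClass), "single class")
})

test_that("linearly separable data trains to perfect accuracy", {
  set.seed(10)
  n <- 120
  lab <- factor(rep(c("healthy", "cancer"), each = n / 2),
                levels = c("healthy", "cancer"))
  x <- cbind(a = as.numeric(lab == "cancer") * 4 + runif(n),
             b = rnorm(n))
  fm <- new("TextureFeatureMatrix", values = x, labels = lab,
            patientIds = rep(c("A", "B", "C"), length.out = n),
            coords = matrix(1L, n, 3, dimnames = list(NULL, c("x", "y", "z"))))
  clf <- trainClassifier(fm)
  m <- scoreMetrics(decisionScores(clf, fm), sampleLabels(fm), clf@threshold)
  expect_equal(unname(m[c("sensitivity", "specificity", "accuracy")]),
               c(1, 1, 1))
})

test_that("confusion metrics match hand arithmetic and flag undefined rates", {
  scores <- c(rep(1, 3), rep(-1, 1), rep(-1, 90), rep(1, 10))
  labels <- factor(c(rep("cancer", 4), rep("healthy", 100)),
                   levels = c("healthy", "cancer"))
  m <- scoreMetrics(scores, labels, 0)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 0.90)
  expect_equal(unname(m["accuracy"]), 93 / 104, tolerance = 1e-9)
  expect_equal(unname(m["accuracy"]), 0.8942, tolerance = 1e-4)
  # perfect separation
  p <- scoreMetrics(c(5, 4, -4, -5), c(TRUE, TRUE, FALSE, FALSE), 0)
  expect_equal(unname(p[1:3]), c(1, 1, 1))
  # undefined rates are NA sentinels, not zeros
  noPos <- scoreMetrics(c(1, -1), factor(c("healthy", "healthy"),
                                         levels = c("healthy", "cancer")), 0)
  expect_true(is.na(noPos["sensitivity"]))
  expect_equal(unname(noPos["specificity"]), 0.5)
  # an all-negative classifier on 1% positives: high accuracy, zero
  # sensitivity -- the report carries all four metrics
  lab2 <- factor(c(rep("cancer", 1), rep("healthy", 99)),
                 levels = c("healthy", "cancer"))
  m2 <- scoreMetrics(rep(-1, 100), lab2, 0)
  expect_equal(unname(m2["accuracy"]), 0.99)
  expect_equal(unname(m2["sensitivity"]), 0)
})

test_that("trapezoid AUC equals the rank-statistic oracle (and pROC) including ties", {
  set.seed(20)
  for (r in 1:30) {
    n <- sample(8:20, 1)
    scores <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE)  # many ties
    labels <- factor(sample(c("healthy", "cancer"), n, replace = TRUE),
                     levels = c("healthy", "cancer"))
    if (length(unique(labels)) < 2) next
    got <- rocAuc(scores, labels)
    expect_equal(got$auc, oracleAuc(scores, labels), tolerance = 1e-12)
    pr <- suppressMessages(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("healthy", "cancer"),
      direction = "<")))
    expect_equal(got$auc, as.numeric(pr), tolerance = 1e-12)
    roc <- got$roc
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  }
  expect_equal(rocAuc(rep(1, 10), factor(rep(c("healthy", "cancer"), 5),
               levels = c("healthy", "cancer")))$auc, 0.5)
  expect_equal(rocAuc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_error(rocAuc(1:3, factor(rep("cancer", 3),
               levels = c("healthy", "cancer"))), "both classes")
})

test_that("patient bootstrap CIs are valid intervals that tighten with cohort size", {
  # identical patients give a degenerate [v, v] interval
  ids <- rep(sprintf("P%d", 1:6), each = 10)
  ci <- bootstrapCI(ids, function(idx) 0.7, reps = 200, seed = 1)
  expect_equal(ci, c(0.7, 0.7))
  # bounds bracket the estimate and stay in [0, 1] for a rate
  set.seed(30)
  vals <- runif(60)
  ciR <- bootstrapCI(ids, function(idx) mean(vals[idx]), reps = 500, seed = 2)
  est <- mean(vals)
  expect_true(ciR[1] <= est && est <= ciR[2])
  expect_true(ciR[1] >= 0 && ciR[2] <= 1)
  # width shrinks roughly like 1/sqrt(n patients)
  width <- function(nPat, seed) {
    set.seed(seed)
    ids <- rep(sprintf("P%02d", seq_len(nPat)), each = 8)
    v <- rnorm(length(ids), 0.5, 0.2)
    diff(bootstrapCI(ids, function(idx) mean(v[idx]), reps = 400, seed = 3))
  }
  w5 <- width(5, 41); w20 <- width(20, 42); w80 <- width(80, 43)
  expect_gt(w5, w20)
  expect_gt(w20, w80)
})

test_that("LOPO evaluation produces coherent pooled and per-patient reports", {
  fm <- syntheticTable(n = 500, nInformative = 3, nNoise = 5,
                       nPatients = 6, effect = 2.5, sd = 0.5, seed = 17)
  rep1 <- evaluateSubset(fm, featureNames(fm), bootReps = 100, seed = 1)
  expect_s4_class(rep1, "EvaluationReport")
  pp <- perPatientMetrics(rep1)
  expect_equal(nrow(pp), 6)
  # pooled confusion equals the sum over patients
  expect_equal(sum(pp$tp) + sum(pp$fn),
               as.integer(rep1@nCancerous))
  expect_equal(sum(pp$tp + pp$fn + pp$tn + pp$fp), rep1@nSamples)
  for (w in c("sensitivity", "specificity", "accuracy", "auc")) {
    e <- pooledMetrics(rep1)[[w]]
    expect_true(e$estimate >= 0 && e$estimate <= 1)
    expect_true(e$ci[1] <= e$estimate + 1e-9 && e$ci[2] >= e$estimate - 1e-9)
  }
  # determinism
  rep2 <- evaluateSubset(fm, featureNames(fm), bootReps = 100, seed = 1)
  expect_equal(pooledMetrics(rep2), pooledMetrics(rep1))
})
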
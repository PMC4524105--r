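TFM_DEFINITIONS <- list(
  TFM1 = c("T2w", "ADC"),
  TFM2 = c("T2w", "ADC", "CHB-DWI"),
  TFM3 = c("T2w", "CDI"),
  TFM4 = c("T2w", "ADC", "CDI"),
  TFM5 = c("T2w", "ADC", "CHB-DWI", "CDI"),
  TFM6 = c("T2w", "ADC", "CHB-DWI", "CDI", "b1", "b2", "b3", "b4")
)

#' Modality composition of the published texture feature models
#'
#' TFM1 = T2w+ADC (the conventional MP-MRI pair); TFM2 adds CHB-DWI;
#' TFM3 = T2w+CDI; TFM4 = T2w+ADC+CDI; TFM5 adds CHB-DWI to TFM4; TFM6
#' additionally includes the four individual b-value images.
#'
#' @param name "TFM1".."TFM6", or missing for the whole list.
#' @return Character vector of modality names (or the named list).
#' @export
tfmModalities <- function(name) {
  if (missing(name)) return(TFM_DEFINITIONS)
  if (!name %in% names(TFM_DEFINITIONS))
    stop("unknown model '", name, "'; expected TFM1..TFM6", call. = FALSE)
  TFM_DEFINITIONS[[name]]
}

modalityOfFeature <- function(featureNames) {
  sub("/.*$", "", featureNames)
}

#' Build a texture feature model by two-stage selection
#'
#' Stage 1 runs criterion-driven subset-size selection
#' ([selectBestM()]) independently on each modality's 96 features.
#' Stage 2 pools the per-modality best subsets. Stage 3 re-runs the
#' selection on the pooled set — under the same criterion, with the
#' final subset size chosen to maximize `target` (by default the
#' criterion itself; e.g. specificity-driven selection may target AUC).
#' A final classifier is then trained on the whole cohort with the
#' selected subset.
#'
#' @param fm a cohort [TextureFeatureMatrix-class] containing all the
#'   model's modalities (build with [extractCohortFeatures()]), or a
#'   named list of sample-aligned per-modality matrices (combined via
#'   [combineFeatureMatrices()]).
#' @param model model name "TFM1".."TFM6", or a character vector of
#'   modality names for a custom model.
#' @param criterion selection criterion used in both stages.
#' @param target metric maximized when picking the final subset size.
#' @param mGridStage1,mGridStage3 candidate subset sizes per stage
#'   (defaults: 10,20,...,96 and steps of 20 over the pooled size).
#' @param seed RNG seed for the CV evaluators.
#' @param ... further arguments passed to the internal grouped-CV SVM
#'   scorer (nGroups, cost, gamma, maxTrainNeg).
#' @return A [TextureFeatureModel-class].
#' @export
buildTFM <- function(fm, model = "TFM6",
                     criterion = c("auc", "sensitivity", "specificity"),
                     target = NULL,
                     mGridStage1 = NULL, mGridStage3 = NULL,
                     seed = 1L, ...) {
  criterion <- match.arg(criterion)
  if (is.null(target)) target <- criterion
  stopIfNot(target %in% c("auc", "sensitivity", "specificity"),
            "target must be auc, sensitivity or specificity")
  if (is.list(fm) && !is(fm, "TextureFeatureMatrix"))
    fm <- combineFeatureMatrices(fm)
  if (length(model) == 1L && model %in% names(TFM_DEFINITIONS)) {
    name <- model
    modalities <- TFM_DEFINITIONS[[model]]
  } else {
    name <- "custom"
    modalities <- as.character(model)
  }
  present <- unique(modalityOfFeature(featureNames(fm)))
  missing <- setdiff(modalities, present)
  if (length(missing))
    stop("feature matrix lacks modalit", if (length(missing) > 1) "ies " else "y ",
         paste(missing, collapse = ", "), call. = FALSE)

  dots <- list(...)
  evalFor <- function(policy) function(fm, subset, seed)
    do.call(cvScore, c(list(fm, subset, thresholdPolicy = policy,
                            seed = seed), dots))

  stage1 <- lapply(setNames(modalities, modalities), function(mod) {
    cols <- featureNames(fm)[modalityOfFeature(featureNames(fm)) == mod]
    sub <- subsetFeatures(fm, cols)
    selectBestM(sub, criterion = criterion, mGrid = mGridStage1,
                evaluator = evalFor(criterion), seed = seed)
  })
  perModalitySubsets <- lapply(stage1, bestSubset)
  pool <- unlist(perModalitySubsets, use.names = FALSE)

  pooled <- subsetFeatures(fm, pool)
  if (is.null(mGridStage3))
    mGridStage3 <- unique(c(seq(10L, length(pool), by = 20L), length(pool)))
  # stage 3: same criterion policy; the *size* is picked on `target`
  stage3 <- selectBestM(pooled, criterion = target, mGrid = mGridStage3,
                        evaluator = evalFor(criterion), seed = seed + 1L)
  final <- bestSubset(stage3)

  policy <- if (criterion %in% c("sensitivity", "specificity"))
    criterion else "youden"
  trainIdx <- capNegatives(fm, seq_along(fm@patientIds),
                           if (!is.null(dots$maxTrainNeg)) dots$maxTrainNeg
                           else 3000L, seed = seed + 5L)
  clf <- trainClassifier(subsetFeatures(fm, final, trainIdx), final,
                         cost = if (!is.null(dots$cost)) dots$cost else 1,
                         gamma = dots$gamma, thresholdPolicy = policy)

  new("TextureFeatureModel",
      name = name, modalities = modalities,
      criterion = criterion, target = target,
      perModalitySubsets = perModalitySubsets,
      finalSubset = final,
      stage1 = stage1, stage3 = stage3,
      classifier = clf)
}

# exact two-sided Wilcoxon signed-rank p for small n without ties,
# normal approximation with continuity correction otherwise; all-zero
# differences are degenerate (p = 1, flagged)
pairedWilcoxon <- function(a, b, exactMax = 12L) {
  keep <- !is.na(a) & !is.na(b)
  d <- a[keep] - b[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p = 1, n = 0L, degenerate = TRUE))
  exact <- n <= exactMax && !any(duplicated(abs(d)))
  p <- suppressWarnings(
    wilcox.test(d, exact = exact, correct = TRUE)$p.value)
  list(p = p, n = n, degenerate = FALSE)
}

#' Compare texture feature models patient-by-patient
#'
#' Evaluates each model with leave-one-patient-out cross-validation on
#' the same cohort (identical patient folds), then compares every model
#' pair metric-by-metric with a two-sided Wilcoxon signed-rank test on
#' the paired per-patient values. Patients for whom a metric is
#' undefined (e.g. sensitivity without cancerous samples) are dropped
#' from that metric's pairing. Comparing a model with itself is
#' degenerate (all differences zero) and reported as p = 1 with a flag.
#'
#' @param models list of [TextureFeatureModel-class] objects (or
#'   precomputed [EvaluationReport-class]s, then `fm` is ignored).
#' @param fm the cohort [TextureFeatureMatrix-class].
#' @param alpha significance level used for the `significant` flag.
#' @param ... passed to [evaluateModel()].
#' @return List with `comparisons` (data.frame: modelA, modelB, metric,
#'   p, n, degenerate, significant) and `reports` (named list of
#'   [EvaluationReport-class]).
#' @export
compareModels <- function(models, fm, alpha = 0.05, ...) {
  isReport <- vapply(models, is, logical(1), "EvaluationReport")
  if (all(isReport)) {
    reports <- models
    if (is.null(names(reports)))
      names(reports) <- paste0("model", seq_along(reports))
  } else {
    reports <- lapply(models, evaluateModel, fm = fm, ...)
    names(reports) <- vapply(models, modelName, character(1))
  }
  stopIfNot(length(reports) >= 2L, "need at least 2 models to compare")
  pats <- lapply(reports, function(r) r@perPatient$patient)
  for (k in seq_along(reports)[-1])
    if (!identical(pats[[k]], pats[[1]]))
      stop("models were evaluated on differing patient folds", call. = FALSE)

  metrics <- c("sensitivity", "specificity", "accuracy", "auc")
  out <- list()
  cmb <- utils::combn(names(reports), 2)
  for (j in seq_len(ncol(cmb))) {
    a <- reports[[cmb[1, j]]]@perPatient
    b <- reports[[cmb[2, j]]]@perPatient
    for (m in metrics) {
      w <- pairedWilcoxon(a[[m]], b[[m]])
      out[[length(out) + 1L]] <- data.frame(
        modelA = cmb[1, j], modelB = cmb[2, j], metric = m,
        p = w$p, n = w$n, degenerate = w$degenerate,
        significant = !w$degenerate && w$p < alpha)
    }
  }
  list(comparisons = do.call(rbind, out), reports = reports)
}
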
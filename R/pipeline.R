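#' Run the full phantom-to-evaluation pipeline
#'
#' Generates a synthetic cohort, derives ADC / CHB-DWI / CDI, extracts
#' the 96-feature texture vector per modality, builds the requested
#' texture feature models by two-stage mRMR selection, and evaluates
#' each with leave-one-patient-out cross-validation. All randomness
#' flows from `seed` (phantom) and `pipelineSeed` (selection CV
#' subsampling and bootstrap), so reruns with identical arguments are
#' identical.
#'
#' Default problem sizes are chosen for a desk-scale run: the phantom
#' default grid with in-plane stride 2 gives a cohort of a few tens of
#' thousands of windows, selection uses 4 patient groups with a coarse
#' subset-size grid, and healthy training samples are capped per fold.
#'
#' @param config a [PhantomConfig-class]; default [phantomConfig()].
#' @param models character vector of model names to build (TFM1..TFM6).
#' @param criterion selection criterion for all models.
#' @param target metric maximized when picking final subset sizes
#'   (default: the criterion).
#' @param stride in-plane window stride for feature extraction.
#' @param mGridStage1,mGridStage3 subset-size grids per stage.
#' @param bootReps patient-bootstrap replicates in the reports.
#' @param pipelineSeed seed for selection/evaluation randomness.
#' @param ... further arguments for the CV scorer (nGroups, cost,
#'   gamma, maxTrainNeg).
#' @return List with `cohort`, `features`, `models` (named list of
#'   [TextureFeatureModel-class]), `reports` (named list of
#'   [EvaluationReport-class]) and `comparisons` (when >= 2 models).
#' @export
runPipeline <- function(config = phantomConfig(),
                        models = c("TFM1", "TFM6"),
                        criterion = "auc", target = NULL,
                        stride = 2L,
                        mGridStage1 = c(10L, 20L, 40L, 96L),
                        mGridStage3 = NULL,
                        bootReps = 500L,
                        pipelineSeed = 1L, ...) {
  cohort <- generateCohort(config)
  cohort <- lapply(cohort, deriveModalities)
  needed <- unique(unlist(lapply(models, tfmModalities)))
  fm <- extractCohortFeatures(cohort, modalities = needed, stride = stride)
  built <- lapply(setNames(models, models), function(m)
    buildTFM(fm, model = m, criterion = criterion, target = target,
             mGridStage1 = mGridStage1, mGridStage3 = mGridStage3,
             seed = pipelineSeed, ...))
  reports <- lapply(built, evaluateModel, fm = fm, bootReps = bootReps,
                    seed = pipelineSeed, ...)
  out <- list(cohort = cohort, features = fm, models = built,
              reports = reports)
  if (length(reports) >= 2L)
    out$comparisons <- compareModels(reports)$comparisons
  out
}
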
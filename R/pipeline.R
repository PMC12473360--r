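## End-to-end orchestration: feature assembly into a SummarizedExperiment,
## per-stage screening and modeling over the three feature sets (VIs,
## NDWTIs, VIs+NDWTIs), and Shapley interpretation of the tuned forest.
## Every stage is deterministic given the pipeline seed.

#' Assemble the per-sample feature table
#'
#' Computes the vegetation indices (from per-patch band means) and the 64
#' wavelet texture features for every sample and returns them as a
#' `SummarizedExperiment`: one `features` assay (features x samples) with
#' `rowData(se)$family` in `{"VI", "WT"}` and `colData` columns `plot_id`,
#' `stage`, `agb`.
#'
#' @param samples list of samples (elements `patches`, `agb`, `stage`,
#'   `plot_id`), e.g. from [generateDataset()] or [loadSamplesFromFiles()].
#' @param registry vegetation-index registry (default the shipped 21-entry
#'   table).
#' @return a `SummarizedExperiment`.
#' @export
assembleFeatures <- function(samples, registry = defaultViRegistry()) {
  vi <- t(vapply(samples, function(s) {
    means <- vapply(bandNames(), function(b)
      roiMeanReflectance(s$patches[[b]]), numeric(1))
    computeAllVis(registry, means)
  }, numeric(length(registry))))
  wt <- t(vapply(samples, function(s) computeWtFeatures(s$patches),
                 numeric(64L)))
  feat <- t(cbind(vi, wt))
  colnames(feat) <- vapply(samples, `[[`, character(1), "plot_id")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feat),
    rowData = S4Vectors::DataFrame(
      family = rep(c("VI", "WT"), c(ncol(vi), ncol(wt)))),
    colData = S4Vectors::DataFrame(
      plot_id = vapply(samples, `[[`, character(1), "plot_id"),
      stage = vapply(samples, `[[`, character(1), "stage"),
      agb = vapply(samples, `[[`, numeric(1), "agb")))
}

#' Load field samples from rasters, an ROI layout and ground truth
#'
#' Reads one multiband TIFF per ROI row (file `<plot_id>.tif` under
#' `rasterDir`, or the `raster` column of the layout when present),
#' extracts the ROI patch and attaches the ground-truth AGB.
#'
#' @param rasterDir directory holding the rasters.
#' @param roiLayoutCsv ROI layout CSV (see [readRoiLayout()]).
#' @param groundTruthCsv ground-truth CSV (see [readGroundTruth()]).
#' @return list of samples suitable for [assembleFeatures()].
#' @export
loadSamplesFromFiles <- function(rasterDir, roiLayoutCsv, groundTruthCsv) {
  rois <- readRoiLayout(roiLayoutCsv)
  gt <- readGroundTruth(groundTruthCsv)
  layout <- read.csv(roiLayoutCsv, stringsAsFactors = FALSE)
  lapply(seq_along(rois), function(i) {
    roi <- rois[[i]]
    file <- if ("raster" %in% names(layout)) layout$raster[i]
            else paste0(roi$plot_id, ".tif")
    img <- readMultibandTiff(file.path(rasterDir, file))
    row <- gt[gt$plot_id == roi$plot_id, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("ground truth must have exactly one row for plot ", roi$plot_id)
    list(agb = row$agb_g_m2, stage = roi$stage, plot_id = roi$plot_id,
         patches = extractRoiPatch(img, roi))
  })
}

#' Screen, model and interpret one growth-stage dataset
#'
#' Runs the per-stage analysis on a [StageDataset-class] built over the
#' combined VI + wavelet-texture matrix: min-max scaling of the texture
#' features (fitted on the training partition), NDWTI construction over all
#' ordered pairs, Spearman screening of both families on the training
#' partition, top-`k` selection (NDWTIs deduplicated across reversed
#' pairs), then MLR and TPE-tuned random forests on the three feature sets
#' (VIs, NDWTIs, fused) plus simple regressions on each family's best
#' feature, and Shapley attributions for the fused forest.
#'
#' @param ds a [StageDataset-class] whose features are the VI columns
#'   followed by the 64 texture columns.
#' @param viNames,wtNames column names of the two families within `ds`.
#' @param k features selected per family (default 5).
#' @param rfTrials TPE trials per forest.
#' @param cvFolds cross-validation folds.
#' @param seed stage-level seed.
#' @param interpret compute Shapley attributions for the fused forest?
#'   (skipping them saves most of the interpretation cost when only the
#'   regression metrics are needed).
#' @param shapEval,shapBackground maximum evaluation/background rows used
#'   for the Shapley computation.
#' @return a list with elements `selection` (per family), `fits` (per
#'   feature set), `metrics` (long data frame), `shap`
#'   ([AttributionMatrix-class]) and `importance`.
#' @export
analyzeStage <- function(ds, viNames, wtNames, k = 5L, rfTrials = 20L,
                         cvFolds = 10L, seed = 1L, interpret = TRUE,
                         shapEval = 40L, shapBackground = 25L) {
  xTr <- trainX(ds); xTe <- testX(ds)
  yTr <- trainY(ds); yTe <- testY(ds)

  scaler <- fitMinMax(xTr[, wtNames, drop = FALSE])
  ndTr <- ndwtiTable(applyMinMax(scaler, xTr[, wtNames, drop = FALSE]))
  ndTe <- ndwtiTable(applyMinMax(scaler, xTe[, wtNames, drop = FALSE]))

  viRep <- rankFeatures(xTr[, viNames, drop = FALSE], yTr, stageOf(ds))
  ndRep <- rankFeatures(ndTr, yTr, stageOf(ds))
  selVi <- selectTopK(viRep, k)
  selNd <- selectTopK(ndRep, k, dedup = TRUE)

  sets <- list(
    VIs = list(tr = xTr[, selVi$feature, drop = FALSE],
               te = xTe[, selVi$feature, drop = FALSE]),
    NDWTIs = list(tr = ndTr[, selNd$feature, drop = FALSE],
                  te = ndTe[, selNd$feature, drop = FALSE]))
  sets[["VIs+NDWTIs"]] <- list(tr = cbind(sets$VIs$tr, sets$NDWTIs$tr),
                               te = cbind(sets$VIs$te, sets$NDWTIs$te))

  fits <- list(
    simple_VI = fitSimpleRegression(xTr[, selVi$feature[1]], yTr,
                                    xTe[, selVi$feature[1]], yTe,
                                    name = selVi$feature[1]),
    simple_NDWTI = fitSimpleRegression(ndTr[, selNd$feature[1]], yTr,
                                       ndTe[, selNd$feature[1]], yTe,
                                       name = selNd$feature[1]))
  for (nm in names(sets)) {
    fits[[paste0("mlr_", nm)]] <-
      fitMlr(sets[[nm]]$tr, yTr, sets[[nm]]$te, yTe)
    fits[[paste0("rf_", nm)]] <-
      fitRfTuned(sets[[nm]]$tr, yTr,
                 modelSpec(nTrials = rfTrials, cvFolds = cvFolds,
                           seed = seed),
                 sets[[nm]]$te, yTe)
  }

  metrics <- do.call(rbind, lapply(names(fits), function(nm) {
    m <- fitMetrics(fits[[nm]])
    cbind(stage = stageOf(ds), model = nm, m)
  }))

  shap <- importance <- shapX <- NULL
  if (interpret) {
    fused <- fits[["rf_VIs+NDWTIs"]]
    set.seed(seed)
    evalRows <- sort(sample.int(nrow(sets[["VIs+NDWTIs"]]$te),
                                min(shapEval,
                                    nrow(sets[["VIs+NDWTIs"]]$te))))
    bgRows <- sort(sample.int(nrow(sets[["VIs+NDWTIs"]]$tr),
                              min(shapBackground,
                                  nrow(sets[["VIs+NDWTIs"]]$tr))))
    shapX <- sets[["VIs+NDWTIs"]]$te[evalRows, , drop = FALSE]
    shap <- shapleyAttributions(fused, shapX,
                                sets[["VIs+NDWTIs"]]$tr[bgRows, ,
                                                        drop = FALSE],
                                seed = seed)
    importance <- summarizeImportance(shap)
  }

  list(selection = list(VI = selVi, NDWTI = selNd),
       reports = list(VI = viRep, NDWTI = head(ndRep, 100L)),
       fits = fits, metrics = metrics, shap = shap,
       importance = importance, shapX = shapX,
       testFeatures = lapply(sets, `[[`, "te"))
}

#' Run the full estimation pipeline
#'
#' Executes extract -> indices -> textures -> NDWTI -> screening -> models
#' -> interpretation for all three growth-stage datasets (pre-heading,
#' post-heading, all-stage), from either in-memory samples or the file
#' interfaces, and optionally writes the flat CSV/YAML artifacts.
#'
#' @param samples list of samples (see [assembleFeatures()]); each must be
#'   labelled `pre_heading` or `post_heading`.
#' @param registry vegetation-index registry.
#' @param k top features per family (default 5).
#' @param trainFraction per-stage training proportion (default 0.75).
#' @param rfTrials TPE trials per forest fit (default 20).
#' @param cvFolds CV folds (default 10).
#' @param seed global pipeline seed; every stochastic stage derives its
#'   seed from it.
#' @param outDir optional output directory for the CSV/YAML artifacts and
#'   the run manifest.
#' @return a list with the `SummarizedExperiment` (`features`), the
#'   `split`, and per-stage analysis results (`stages`), invisibly when
#'   `outDir` is given.
#' @export
runPipeline <- function(samples, registry = defaultViRegistry(), k = 5L,
                        trainFraction = 0.75, rfTrials = 20L, cvFolds = 10L,
                        seed = 1L, interpret = TRUE, outDir = NULL) {
  se <- assembleFeatures(samples, registry)
  feat <- t(SummarizedExperiment::assay(se, "features"))
  cd <- SummarizedExperiment::colData(se)
  viNames <- rownames(se)[SummarizedExperiment::rowData(se)$family == "VI"]
  wtNames <- rownames(se)[SummarizedExperiment::rowData(se)$family == "WT"]

  split <- splitStagewise(feat, cd$agb, cd$stage,
                          trainFraction = trainFraction, seed = seed)
  stages <- lapply(seq_along(split), function(i)
    analyzeStage(split[[i]], viNames, wtNames, k = k, rfTrials = rfTrials,
                 cvFolds = cvFolds, seed = seed + i,
                 interpret = interpret))
  names(stages) <- names(split)

  res <- list(features = se, split = split, stages = stages,
              metrics = do.call(rbind, lapply(stages, `[[`, "metrics")),
              seed = seed)
  rownames(res$metrics) <- NULL

  if (!is.null(outDir)) {
    writePipelineArtifacts(res, outDir, k = k, rfTrials = rfTrials,
                           cvFolds = cvFolds)
    return(invisible(res))
  }
  res
}

writePipelineArtifacts <- function(res, outDir, ...) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  se <- res$features
  feat <- t(SummarizedExperiment::assay(se, "features"))
  df <- cbind(as.data.frame(SummarizedExperiment::colData(se)),
              as.data.frame(feat))
  write.csv(df, file.path(outDir, "features.csv"), row.names = FALSE)
  write.csv(res$metrics, file.path(outDir, "metrics.csv"), row.names = FALSE)
  sel <- lapply(res$stages, function(s)
    lapply(s$selection, function(x) as.list(setNames(x$rho, x$feature))))
  yaml::write_yaml(sel, file.path(outDir, "selection.yaml"))
  models <- lapply(res$stages, function(s)
    lapply(s$fits[grepl("^rf_", names(s$fits))], function(f)
      fitHyperparameters(f)[c("n_estimators", "max_depth",
                              "min_samples_split", "min_samples_leaf",
                              "max_features", "max_features_frac",
                              "cv_r2")]))
  yaml::write_yaml(models, file.path(outDir, "models.yaml"))
  preds <- do.call(rbind, lapply(names(res$stages), function(nm) {
    st <- res$stages[[nm]]
    do.call(rbind, lapply(names(st$testFeatures), function(setName) {
      fit <- st$fits[[paste0("rf_", setName)]]
      data.frame(stage = nm, feature_set = setName, partition = "test",
                 observed = testY(res$split[[nm]]),
                 predicted = predictFit(fit, st$testFeatures[[setName]]))
    }))
  }))
  write.csv(preds, file.path(outDir, "predictions.csv"), row.names = FALSE)
  for (nm in names(res$stages)) {
    s <- res$stages[[nm]]
    write.csv(s$reports$VI,
              file.path(outDir, paste0("correlation_", nm, "_VI.csv")),
              row.names = FALSE)
    write.csv(s$reports$NDWTI,
              file.path(outDir, paste0("correlation_", nm, "_NDWTI.csv")),
              row.names = FALSE)
    if (!is.null(s$shap)) {
      write.csv(cbind(as.data.frame(attributionValues(s$shap)),
                      .base = attributionBase(s$shap)),
                file.path(outDir, paste0("shap_", nm, ".csv")),
                row.names = FALSE)
      write.csv(s$importance,
                file.path(outDir, paste0("importance_", nm, ".csv")),
                row.names = FALSE)
    }
  }
  manifest <- c(list(seed = res$seed,
                     n_samples = ncol(se),
                     n_features = nrow(se),
                     stages = names(res$stages),
                     package_version =
                       as.character(utils::packageVersion("waveCanopy"))),
                list(...))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(outDir)
}
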
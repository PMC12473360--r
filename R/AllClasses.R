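#' @import methods
#' @importFrom stats cor dnorm lm.fit pnorm qnorm quantile rnorm runif rpois
#'   sd shapiro.test var predict setNames
#' @importFrom utils read.csv write.csv head
NULL

## Canonical band handling ----------------------------------------------------

#' Canonical band names
#'
#' The package works on four-band reflectance imagery. Internally bands are
#' keyed by the lower-case identifiers `green`, `red`, `red_edge`, `nir`;
#' feature names use the display labels `Green`, `Red`, `Red-edge`, `NIR`.
#'
#' @return `bandNames()` returns the four internal band keys in canonical
#'   order; `bandLabels()` the corresponding display labels.
#' @examples
#' bandNames()
#' bandLabels()
#' @export
bandNames <- function() c("green", "red", "red_edge", "nir")

#' @rdname bandNames
#' @export
bandLabels <- function() c(green = "Green", red = "Red",
                           red_edge = "Red-edge", nir = "NIR")

subbandNames <- function() c("LL", "LH", "HL", "HH")
statNames    <- function() c("Mea", "Var", "Ene", "Ent")

## SceneConfig -----------------------------------------------------------------

#' @rdname sceneConfig
#' @export
setClass("SceneConfig",
  representation(
    plotRows       = "integer",
    plotCols       = "integer",
    patchSize      = "integer",
    stage          = "character",
    agbRange       = "numeric",
    coverageGain   = "numeric",
    speckleDensity = "numeric",
    noiseSd        = "numeric",
    seed           = "integer",
    canopyRefl     = "numeric",
    soilRefl       = "numeric",
    reflJitterSd   = "numeric",
    speckleGain    = "numeric"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@plotRows < 1L || object@plotCols < 1L)
    msg <- c(msg, "plot layout must have at least one row and one column")
  if (object@patchSize < 8L || object@patchSize %% 2L != 0L)
    msg <- c(msg, "patchSize must be >= 8 and even")
  if (!object@stage %in% c("pre_heading", "post_heading"))
    msg <- c(msg, "stage must be 'pre_heading' or 'post_heading'")
  if (length(object@agbRange) != 2L || any(object@agbRange <= 0) ||
      diff(object@agbRange) <= 0)
    msg <- c(msg, "agbRange must be a positive increasing interval")
  if (object@coverageGain <= 0)
    msg <- c(msg, "coverageGain must be positive")
  if (object@speckleDensity < 0 || object@noiseSd < 0)
    msg <- c(msg, "speckleDensity and noiseSd must be non-negative")
  if (!identical(sort(names(object@canopyRefl)), sort(bandNames())) ||
      !identical(sort(names(object@soilRefl)), sort(bandNames())))
    msg <- c(msg, "canopyRefl and soilRefl must name all four bands")
  # saturating link keeps cover in [0, 1) automatically; reflectances physical
  if (any(object@canopyRefl < 0) || any(object@soilRefl < 0))
    msg <- c(msg, "reflectance constants must be non-negative")
  if (length(msg)) msg else TRUE
})

## MultibandImage --------------------------------------------------------------

#' @rdname MultibandImage
#' @export
setClass("MultibandImage",
  representation(
    bands  = "list",
    nodata = "numeric"   # length 0 when absent
  )
)

setValidity("MultibandImage", function(object) {
  msg <- character()
  missing <- setdiff(bandNames(), names(object@bands))
  if (length(missing))
    msg <- c(msg, paste0("missing band(s): ", paste(missing, collapse = ", ")))
  dims <- lapply(object@bands, dim)
  if (length(dims) > 1L &&
      !all(vapply(dims, identical, logical(1), dims[[1]])))
    msg <- c(msg, "all bands must share identical dimensions")
  if (length(msg)) msg else TRUE
})

## StageDataset ----------------------------------------------------------------

#' @rdname StageDataset
#' @export
setClass("StageDataset",
  representation(
    stage        = "character",
    xTrain       = "matrix",
    xTest        = "matrix",
    yTrain       = "numeric",
    yTest        = "numeric",
    featureNames = "character"
  )
)

setValidity("StageDataset", function(object) {
  msg <- character()
  if (nrow(object@xTrain) != length(object@yTrain))
    msg <- c(msg, "xTrain rows must match yTrain length")
  if (nrow(object@xTest) != length(object@yTest))
    msg <- c(msg, "xTest rows must match yTest length")
  if (ncol(object@xTrain) != length(object@featureNames) ||
      ncol(object@xTest) != length(object@featureNames))
    msg <- c(msg, "feature count mismatch")
  if (length(msg)) msg else TRUE
})

## FitResult -------------------------------------------------------------------

#' @rdname FitResult
#' @export
setClass("FitResult",
  representation(
    kind            = "character",    # "simple", "mlr", "rf"
    model           = "ANY",
    hyperparameters = "list",
    metrics         = "data.frame",   # partition, r2, rmse
    coefficients    = "numeric",      # named, length 0 for rf
    featureNames    = "character",
    scaling         = "list"          # z-score centre/scale for rf, empty else
  )
)

setValidity("FitResult", function(object) {
  msg <- character()
  if (!object@kind %in% c("simple", "mlr", "rf"))
    msg <- c(msg, "kind must be one of 'simple', 'mlr', 'rf'")
  ok <- all(c("partition", "r2", "rmse") %in% names(object@metrics))
  if (!ok) msg <- c(msg, "metrics must have partition/r2/rmse columns")
  else if (any(object@metrics$rmse < 0, na.rm = TRUE))
    msg <- c(msg, "RMSE must be non-negative")
  if (length(msg)) msg else TRUE
})

## AttributionMatrix -----------------------------------------------------------

#' @rdname AttributionMatrix
#' @export
setClass("AttributionMatrix",
  representation(
    values    = "matrix",     # samples x features, g/m2 contribution scale
    baseValue = "numeric",
    predicted = "numeric"
  )
)

setValidity("AttributionMatrix", function(object) {
  msg <- character()
  if (length(object@baseValue) != 1L)
    msg <- c(msg, "baseValue must be a single number")
  if (length(object@predicted) != nrow(object@values))
    msg <- c(msg, "predicted length must match attribution rows")
  recon <- object@baseValue + rowSums(object@values)
  tol <- 1e-6 * pmax(abs(object@predicted), 1)
  if (any(abs(recon - object@predicted) > tol))
    msg <- c(msg, "local accuracy violated: base + sum(attributions) != prediction")
  if (length(msg)) msg else TRUE
})

## show methods ----------------------------------------------------------------

setMethod("show", "SceneConfig", function(object) {
  cat("SceneConfig:", object@plotRows, "x", object@plotCols, "plots,",
      "patch", object@patchSize, "px,", object@stage, "\n")
  cat("  AGB range:", paste(object@agbRange, collapse = "-"), "g/m2,",
      "coverage gain:", object@coverageGain, "\n")
  cat("  speckle density:", object@speckleDensity,
      " noise sd:", object@noiseSd, " seed:", object@seed, "\n")
})

setMethod("show", "MultibandImage", function(object) {
  d <- dim(object@bands[[1]])
  cat("MultibandImage:", d[1], "x", d[2], "px,",
      length(object@bands), "bands (", paste(names(object@bands),
      collapse = ", "), ")\n")
})

setMethod("show", "StageDataset", function(object) {
  cat("StageDataset [", object@stage, "]: ",
      nrow(object@xTrain), " train / ", nrow(object@xTest), " test samples, ",
      length(object@featureNames), " features\n", sep = "")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult <", object@kind, "> on ", length(object@featureNames),
      " feature(s)\n", sep = "")
  print(object@metrics, row.names = FALSE)
})

setMethod("show", "AttributionMatrix", function(object) {
  cat("AttributionMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "features, base value",
      signif(object@baseValue, 6), "\n")
})

## Accessors -------------------------------------------------------------------

#' Accessors for waveCanopy S4 objects
#'
#' Small getter functions so user code never reaches into slots.
#'
#' @param x a `StageDataset`, `FitResult`, `AttributionMatrix` or
#'   `MultibandImage` object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
stageOf <- function(x) x@stage

#' @rdname accessors
#' @export
trainX <- function(x) x@xTrain

#' @rdname accessors
#' @export
testX <- function(x) x@xTest

#' @rdname accessors
#' @export
trainY <- function(x) x@yTrain

#' @rdname accessors
#' @export
testY <- function(x) x@yTest

#' @rdname accessors
#' @export
featureNames <- function(x) x@featureNames

#' @rdname accessors
#' @export
fitMetrics <- function(x) x@metrics

#' @rdname accessors
#' @export
fitHyperparameters <- function(x) x@hyperparameters

#' @rdname accessors
#' @export
fitCoefficients <- function(x) x@coefficients

#' @rdname accessors
#' @export
attributionValues <- function(x) x@values

#' @rdname accessors
#' @export
attributionBase <- function(x) x@baseValue

#' @rdname accessors
#' @export
imageBands <- function(x) x@bands
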
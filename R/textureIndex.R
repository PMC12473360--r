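## Min-max scaling of the 64 wavelet texture features and construction of
## normalized-difference wavelet texture indices (NDWTI) over all ordered
## feature pairs. Low-frequency means the LL subband; LH/HL/HH are
## high-frequency. With 16 low and 48 high features the ordered-pair counts
## are 240 low-low, 2256 high-high and 1536 mixed = 4032 in total.

#' Fit a per-feature min-max scaler
#'
#' Learns per-column `(min, max)` from a training feature matrix. Scaling is
#' always fitted on the training partition only and then applied to held-out
#' data, avoiding information leakage.
#'
#' @param trainingFeatures numeric matrix (samples x features) with column
#'   names.
#' @return a `minmax_params` object.
#' @export
fitMinMax <- function(trainingFeatures) {
  if (!is.matrix(trainingFeatures) || nrow(trainingFeatures) < 2L)
    stop("need a matrix with at least 2 training samples")
  if (is.null(colnames(trainingFeatures)))
    stop("feature matrix must have column names")
  structure(list(min = apply(trainingFeatures, 2L, min),
                 max = apply(trainingFeatures, 2L, max)),
            class = "minmax_params")
}

#' Apply a fitted min-max scaler
#'
#' Maps each feature to `(x - min) / (max - min)` using the training-time
#' range. Values outside the training range map outside `[0, 1]`; no
#' clipping is applied. Constant training columns (`max == min`) map to
#' zero.
#'
#' @param params a `minmax_params` from [fitMinMax()].
#' @param features numeric matrix (or single named row) with the fitted
#'   feature names.
#' @return the scaled matrix.
#' @export
applyMinMax <- function(params, features) {
  if (!inherits(params, "minmax_params")) stop("params must be fitted first")
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
    dimnames = list(NULL, names(features)))
  unknown <- setdiff(colnames(features), names(params$min))
  if (length(unknown))
    stop("unknown feature name(s): ", paste(head(unknown, 3), collapse = ", "))
  nm <- colnames(features)
  rng <- params$max[nm] - params$min[nm]
  out <- sweep(features, 2L, params$min[nm], `-`)
  out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), `/`)
  out[, rng == 0] <- 0   # zero-range convention
  out
}

subbandClass <- function(featureName) {
  sb <- sub("_.*$", "", featureName)
  ifelse(sb == "LL", "low", "high")
}

#' Enumerate all ordered NDWTI feature pairs
#'
#' Every ordered pair `(wt1, wt2)` with `wt1 != wt2` over the supplied
#' feature names, labelled by frequency class: `low_low` (both LL),
#' `high_high` (both detail subbands), `low_high` (mixed, either order).
#' Over the canonical 64 features this gives 4032 pairs
#' (2256 high-high, 240 low-low, 1536 mixed).
#'
#' @param featureNames unique feature names (canonically
#'   [wtFeatureNames()]).
#' @param classFilter optional class to keep: `"low_low"`, `"high_high"`
#'   or `"low_high"`.
#' @return a data frame with columns `wt1`, `wt2`, `class`, `name` where
#'   `name` is `"NDWTI(<wt1>-<wt2>)"`.
#' @examples
#' nrow(enumeratePairs(wtFeatureNames()))  # 4032
#' @export
enumeratePairs <- function(featureNames, classFilter = NULL) {
  if (anyDuplicated(featureNames)) stop("feature names must be unique")
  grid <- expand.grid(wt2 = featureNames, wt1 = featureNames,
                      stringsAsFactors = FALSE)[, c("wt1", "wt2")]
  grid <- grid[grid$wt1 != grid$wt2, , drop = FALSE]
  c1 <- subbandClass(grid$wt1)
  c2 <- subbandClass(grid$wt2)
  grid$class <- ifelse(c1 == "low" & c2 == "low", "low_low",
                ifelse(c1 == "high" & c2 == "high", "high_high", "low_high"))
  if (!is.null(classFilter)) {
    stopifnot(classFilter %in% c("low_low", "high_high", "low_high"))
    grid <- grid[grid$class == classFilter, , drop = FALSE]
  }
  grid$name <- sprintf("NDWTI(%s-%s)", grid$wt1, grid$wt2)
  rownames(grid) <- NULL
  grid
}

#' Normalized-difference wavelet texture index
#'
#' `NDWTI = (WT1 - WT2) / (WT1 + WT2)` on min-max-scaled wavelet texture
#' features. When `|WT1 + WT2|` falls below 1e-12 (both features at their
#' training minimum) the symmetric limit 0 is returned.
#'
#' @param wt1Scaled,wt2Scaled scaled feature values (vectors allowed).
#' @return the index value(s), antisymmetric in its arguments.
#' @examples
#' computeNdwti(0.8, 0.2)  # 0.6
#' @export
computeNdwti <- function(wt1Scaled, wt2Scaled) {
  s <- wt1Scaled + wt2Scaled
  ifelse(abs(s) < 1e-12, 0, (wt1Scaled - wt2Scaled) / s)
}

#' NDWTI table for a set of samples
#'
#' Computes every enumerated pair index from a scaled feature matrix.
#'
#' @param scaled scaled wavelet-texture matrix (samples x 64), as produced
#'   by [applyMinMax()].
#' @param pairs pair table from [enumeratePairs()]; defaults to all ordered
#'   pairs over the columns of `scaled`.
#' @return numeric matrix (samples x pairs) with the pair `name`s as
#'   columns.
#' @export
ndwtiTable <- function(scaled, pairs = enumeratePairs(colnames(scaled))) {
  out <- computeNdwti(scaled[, pairs$wt1, drop = FALSE],
                      scaled[, pairs$wt2, drop = FALSE])
  dimnames(out) <- list(rownames(scaled), pairs$name)
  out
}

#' Parse an NDWTI column name back into its feature pair
#'
#' @param name character vector of names of the form
#'   `"NDWTI(<wt1>-<wt2>)"` built from canonical feature names.
#' @return data frame with columns `wt1`, `wt2`.
#' @export
parseNdwtiName <- function(name) {
  feat <- "(LL|LH|HL|HH)_(Green|Red-edge|Red|NIR)_(Mea|Var|Ene|Ent)"
  rx <- paste0("^NDWTI\\((", feat, ")-(", feat, ")\\)$")
  ok <- grepl(rx, name)
  if (any(!ok)) stop("not a canonical NDWTI name: ", name[!ok][1])
  data.frame(wt1 = sub(rx, "\\1", name), wt2 = sub(rx, "\\5", name),
             stringsAsFactors = FALSE)
}
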
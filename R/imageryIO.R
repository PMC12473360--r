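## Multiband raster I/O and per-plot patch extraction. Rasters are plain
## multiband TIFF (32-bit float, band order green, red, red-edge, nir);
## plot ROIs are pixel-space rectangles in 0-based half-open indexing.

#' Four-band reflectance image
#'
#' `MultibandImage` holds one 2-D reflectance array per band plus an
#' optional nodata sentinel. All bands must share dimensions and the band
#' set must contain `green`, `red`, `red_edge`, `nir`.
#'
#' @name MultibandImage
#' @aliases MultibandImage-class
NULL

#' Construct a MultibandImage from band matrices
#'
#' @param bands named list of equal-sized matrices covering at least the
#'   four canonical bands.
#' @param nodata optional numeric sentinel marking invalid pixels.
#' @return a validated [MultibandImage-class].
#' @export
multibandImage <- function(bands, nodata = numeric()) {
  new("MultibandImage", bands = bands, nodata = as.numeric(nodata))
}

#' Read a multiband reflectance raster
#'
#' Reads a multiband TIFF written with [writeMultibandTiff()] (band order
#' green, red, red-edge, nir). Reflectances are returned exactly as stored;
#' no rescaling is applied.
#'
#' @param path file path.
#' @param nodata optional nodata sentinel to attach.
#' @return a [MultibandImage-class].
#' @export
readMultibandTiff <- function(path, nodata = numeric()) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  # 4-sample TIFFs trigger a benign reader note about non-colour channels
  arr <- withCallingHandlers(
    tiff::readTIFF(path, as.is = FALSE),
    warning = function(w) {
      if (grepl("ExtraSamples", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (dim(arr)[3] < 4L)
    stop("raster has ", dim(arr)[3], " band(s); need 4 (missing ",
         paste(bandNames()[seq(dim(arr)[3] + 1L, 4L)], collapse = ", "), ")")
  bands <- lapply(seq_len(4L), function(k) arr[, , k])
  names(bands) <- bandNames()
  multibandImage(bands, nodata)
}

#' Write a multiband reflectance raster
#'
#' @param image a [MultibandImage-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeMultibandTiff <- function(image, path) {
  validObject(image)
  b <- image@bands[bandNames()]
  arr <- array(0, c(dim(b[[1]]), 4L))
  for (k in seq_len(4L)) arr[, , k] <- b[[k]]
  tiff::writeTIFF(arr, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Define a rectangular plot ROI
#'
#' Pixel-space rectangle in 0-based, half-open indexing: rows
#' `[row0, row1)`, columns `[col0, col1)`.
#'
#' @param plotId identifier.
#' @param row0,row1,col0,col1 integer bounds.
#' @param stage growth-stage label.
#' @param year optional trial year.
#' @return a `plot_roi` list.
#' @export
plotRoi <- function(plotId, row0, row1, col0, col1,
                    stage = NA_character_, year = NA_integer_) {
  if (row1 <= row0 || col1 <= col0) stop("ROI bounds must be non-empty")
  if (row0 < 0 || col0 < 0) stop("ROI bounds must be non-negative")
  structure(list(plot_id = plotId, row0 = as.integer(row0),
                 row1 = as.integer(row1), col0 = as.integer(col0),
                 col1 = as.integer(col1), stage = stage,
                 year = as.integer(year)),
            class = "plot_roi")
}

#' Read an ROI layout table
#'
#' CSV with columns `plot_id,row0,row1,col0,col1,stage,year` (0-based
#' half-open pixel rectangles).
#'
#' @param path CSV path.
#' @return a list of `plot_roi` objects.
#' @export
readRoiLayout <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "row0", "row1", "col0", "col1")
  if (!all(need %in% names(df)))
    stop("ROI layout must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    plotRoi(df$plot_id[i], df$row0[i], df$row1[i], df$col0[i], df$col1[i],
            stage = if ("stage" %in% names(df)) df$stage[i] else NA_character_,
            year = if ("year" %in% names(df)) df$year[i] else NA_integer_))
}

#' Extract the per-band patches of one ROI
#'
#' The ROI must lie fully inside the image; partial overlap is an error,
#' never a silent clip. If the image carries a nodata sentinel and the ROI
#' contains nodata pixels, behaviour follows `onNodata`: `"error"`
#' (default) or `"mask"` (pixels set to `NA` with a warning).
#'
#' @param image a [MultibandImage-class].
#' @param roi a `plot_roi`.
#' @param onNodata `"error"` or `"mask"`.
#' @return named list of four patch matrices.
#' @export
extractRoiPatch <- function(image, roi, onNodata = c("error", "mask")) {
  onNodata <- match.arg(onNodata)
  validObject(image)
  d <- dim(image@bands[[1]])
  if (roi$row1 > d[1] || roi$col1 > d[2])
    stop("ROI '", roi$plot_id, "' extends outside the image extent (",
         d[1], " x ", d[2], " px)")
  rows <- (roi$row0 + 1L):roi$row1   # 0-based half-open -> R indices
  cols <- (roi$col0 + 1L):roi$col1
  patches <- lapply(image@bands[bandNames()], function(b)
    b[rows, cols, drop = FALSE])
  if (length(image@nodata)) {
    bad <- Reduce(`|`, lapply(patches, function(p) p == image@nodata))
    if (any(bad)) {
      if (onNodata == "error")
        stop("ROI '", roi$plot_id, "' contains ", sum(bad), " nodata pixel(s)")
      warning("masking ", sum(bad), " nodata pixel(s) in ROI '",
              roi$plot_id, "'")
      patches <- lapply(patches, function(p) { p[bad] <- NA_real_; p })
    }
  }
  patches
}

#' Mean reflectance of a patch
#'
#' Arithmetic mean over unmasked (non-`NA`) pixels.
#'
#' @param patch a numeric matrix, possibly with `NA` for masked pixels.
#' @return the mean reflectance.
#' @export
roiMeanReflectance <- function(patch) {
  if (length(patch) == 0L) stop("empty patch")
  if (all(is.na(patch))) stop("all pixels masked")
  mean(patch, na.rm = TRUE)
}

#' Convert a sample dry weight to AGB per unit area
#'
#' `AGB = T / S` with `T` the total dry weight (g) of the quadrat sample and
#' `S` the quadrat ground area (m2); the conventional 0.5 m x 0.5 m quadrat
#' gives `S = 0.25`.
#'
#' @param totalDryWeight dry weight in grams, >= 0.
#' @param area quadrat area in m2, > 0 (default 0.25).
#' @return AGB in g/m2.
#' @examples
#' agbFromSampleWeight(200, 0.25)  # 800 g/m2
#' @export
agbFromSampleWeight <- function(totalDryWeight, area = 0.25) {
  if (any(area <= 0)) stop("area must be positive")
  if (any(totalDryWeight < 0)) stop("dry weight must be non-negative")
  totalDryWeight / area
}

#' Read a ground-truth AGB table
#'
#' CSV with columns `plot_id`, `stage`, `agb_g_m2`.
#'
#' @param path CSV path.
#' @return a data frame.
#' @export
readGroundTruth <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "stage", "agb_g_m2")
  if (!all(need %in% names(df)))
    stop("ground truth must have columns: ", paste(need, collapse = ", "))
  if (any(df$agb_g_m2 <= 0)) stop("AGB values must be positive")
  df
}
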
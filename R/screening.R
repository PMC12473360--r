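## Stage-wise feature screening: Spearman rank correlation against AGB,
## Shapiro-Wilk normality reporting, and top-k selection with antisymmetric
## NDWTI deduplication. The Shapiro-Wilk p-values justify the rank-based
## correlation (most reflectance-derived features are non-normal); they gate
## nothing. No multiple-testing correction is applied across the 4032
## screening correlations -- selection is by effect size (|rho|), not by
## p-value; treat the screening p-values, if computed, as descriptive.

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive midranks). Returns the
#' undefined-value sentinel `NA` when either vector is constant.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA`.
#' @examples
#' spearmanRho(1:3, c(2, 4, 6))   # 1
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard test, returning the statistic and
#' p-value; sample size must be between 3 and 5000.
#'
#' @param x numeric vector.
#' @return named vector `c(W, p)`.
#' @export
shapiroWilk <- function(x) {
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  fit <- shapiro.test(x)
  c(W = unname(fit$statistic), p = unname(fit$p.value))
}

#' Rank features by |Spearman correlation| with AGB
#'
#' One report row per feature, ordered by descending `abs_rho` (ties broken
#' by feature name for run-to-run stability). Features whose correlation is
#' undefined (constant columns) are dropped with a warning.
#'
#' @param featureMatrix samples x features matrix with column names.
#' @param agb AGB vector aligned with the rows.
#' @param stage stage label carried into the report.
#' @return data frame with columns `feature`, `rho`, `abs_rho`, `n`,
#'   `stage`.
#' @export
rankFeatures <- function(featureMatrix, agb, stage = NA_character_) {
  if (nrow(featureMatrix) != length(agb))
    stop("featureMatrix rows and agb length differ")
  # rank once, correlate all columns in one pass
  ry <- rank(agb)
  rx <- apply(featureMatrix, 2L, rank)
  keep <- apply(featureMatrix, 2L, function(col) sd(col) != 0) &
    !apply(featureMatrix, 2L, anyNA)
  if (sd(agb) == 0) stop("AGB vector is constant; correlation undefined")
  if (any(!keep))
    warning(sum(!keep), " feature(s) dropped: undefined correlation ",
            "(constant or missing values)")
  rho <- suppressWarnings(as.vector(cor(rx[, keep, drop = FALSE], ry)))
  rep <- data.frame(feature = colnames(featureMatrix)[keep], rho = rho,
                    abs_rho = abs(rho), n = length(agb), stage = stage,
                    stringsAsFactors = FALSE)
  rep[order(-rep$abs_rho, rep$feature), , drop = FALSE]
}

#' Select the top-k screened features
#'
#' Takes the `k` features with the largest `|rho|`. With `dedup = TRUE`
#' (intended for NDWTI candidates) a pair and its reversal -- whose
#' correlations are equal in magnitude by antisymmetry -- count as one
#' candidate, keeping the lexicographically smaller ordered name. Exact
#' `|rho|` ties between distinct candidates are broken lexicographically,
#' so selection is stable across runs.
#'
#' @param reports report data frame from [rankFeatures()].
#' @param k number of features to keep (default 5).
#' @param dedup collapse antisymmetric NDWTI duplicates first?
#' @return data frame of the selected rows (fewer than `k` with a warning
#'   when not enough valid candidates exist).
#' @export
selectTopK <- function(reports, k = 5L, dedup = FALSE) {
  if (k < 1L) stop("k must be >= 1")
  rep <- reports[order(-reports$abs_rho, reports$feature), , drop = FALSE]
  if (dedup) {
    pr <- parseNdwtiName(rep$feature)
    key <- ifelse(pr$wt1 < pr$wt2,
                  paste(pr$wt1, pr$wt2), paste(pr$wt2, pr$wt1))
    # within a duplicate pair keep the lexicographically smaller full name
    ord <- order(key, rep$feature)
    rep <- rep[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    rep <- rep[order(-rep$abs_rho, rep$feature), , drop = FALSE]
  }
  if (nrow(rep) < k) {
    warning("only ", nrow(rep), " valid feature(s) available; returning all")
    k <- nrow(rep)
  }
  out <- rep[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
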
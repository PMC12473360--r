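## Shapley-value attributions for the fitted models. For p features the
## interventional value function is v(S) = mean over background rows b of
## f(x_S, b_{~S}); with p <= 15 all 2^p coalitions are enumerated and the
## Shapley weights applied exactly, otherwise a seeded permutation-sampling
## estimator is used. Both routes satisfy local accuracy exactly:
## base value + sum of attributions = model prediction for every sample.

modelPredictor <- function(model) {
  if (is(model, "FitResult")) return(function(M) predictFit(model, M))
  if (is.function(model)) return(model)
  stop("unsupported model kind: supply a FitResult or a prediction function")
}

shapleyExactOne <- function(predf, x, background, weights, masks) {
  p <- length(x)
  nb <- nrow(background)
  nMask <- nrow(masks)
  # hybrid rows: for every coalition, every background row
  hyb <- background[rep(seq_len(nb), times = nMask), , drop = FALSE]
  maskRep <- masks[rep(seq_len(nMask), each = nb), , drop = FALSE]
  xRep <- matrix(x, nrow(hyb), p, byrow = TRUE)
  hyb[maskRep] <- xRep[maskRep]
  v <- rowsum(predf(hyb), rep(seq_len(nMask), each = nb)) / nb
  phi <- numeric(p)
  sizes <- rowSums(masks)
  for (i in seq_len(p)) {
    without <- which(!masks[, i])
    with_i <- without + 2L^(i - 1L)          # mask ids are 1 + sum 2^(j-1)
    phi[i] <- sum(weights[sizes[without] + 1L] * (v[with_i] - v[without]))
  }
  phi
}

#' Shapley attributions for a fitted model
#'
#' Computes per-sample, per-feature Shapley values of the model output
#' (g/m2 contribution scale) against a background dataset, exactly (all
#' coalitions) for up to 15 features and by seeded permutation sampling
#' beyond that. The base value is the mean model output over the
#' background; local accuracy holds for every sample.
#'
#' @param model a [FitResult-class] (any kind) or a prediction function
#'   `f(matrix) -> numeric`.
#' @param X samples to explain (matrix with named columns).
#' @param background background/reference matrix (defaults to `X`); for
#'   large training sets pass a subsample.
#' @param nPermutations permutations for the sampling fallback
#'   (default 1024).
#' @param seed RNG seed for the sampling fallback.
#' @return an [AttributionMatrix-class].
#' @export
shapleyAttributions <- function(model, X, background = X,
                                nPermutations = 1024L, seed = 1L) {
  predf <- modelPredictor(model)
  X <- as.matrix(X)
  background <- as.matrix(background)[, colnames(X), drop = FALSE]
  p <- ncol(X)
  base <- mean(predf(background))
  pred <- predf(X)

  if (p <= 15L) {
    # coalition masks ordered so that mask id = 1 + sum over members 2^(i-1)
    masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
    dimnames(masks) <- NULL
    sizes <- 0:(p - 1L)
    weights <- exp(lfactorial(sizes) + lfactorial(p - sizes - 1L) -
                   lfactorial(p))
    phi <- t(vapply(seq_len(nrow(X)), function(r)
      shapleyExactOne(predf, X[r, ], background, weights, masks),
      numeric(p)))
  } else {
    set.seed(seed)
    phi <- matrix(0, nrow(X), p)
    for (m in seq_len(nPermutations)) {
      perm <- sample.int(p)
      b <- background[sample.int(nrow(background), 1L), ]
      cur <- matrix(b, nrow(X), p, byrow = TRUE)
      colnames(cur) <- colnames(X)
      prev <- predf(cur)
      for (i in perm) {
        cur[, i] <- X[, i]
        now <- predf(cur)
        phi[, i] <- phi[, i] + (now - prev)
        prev <- now
      }
    }
    phi <- phi / nPermutations
    # permutation average telescopes to f(x) - f(b); recentre the residual
    # background-draw noise uniformly so local accuracy is exact
    resid <- (pred - base) - rowSums(phi)
    phi <- phi + resid / p
  }
  dimnames(phi) <- list(rownames(X), colnames(X))
  new("AttributionMatrix", values = phi, baseValue = base, predicted = pred)
}

#' Z-score standardization of attributions
#'
#' Standardizes each feature's attribution column to mean 0, unit variance
#' (population moments). Constant columns map to zero with a warning.
#'
#' @param att an [AttributionMatrix-class] (or bare matrix).
#' @return matrix of standardized (dimensionless) attribution scores.
#' @export
standardizeAttributions <- function(att) {
  M <- if (is(att, "AttributionMatrix")) attributionValues(att) else att
  if (nrow(M) < 2L) stop("need at least 2 evaluation samples")
  mu <- colMeans(M)
  sig <- sqrt(colMeans(sweep(M, 2L, mu)^2))   # population sd
  if (any(sig == 0)) {
    warning(sum(sig == 0), " constant attribution column(s) set to zero")
    sig[sig == 0] <- Inf
  }
  sweep(sweep(M, 2L, mu), 2L, sig, `/`)
}

#' Rank features by mean absolute attribution
#'
#' @param att an [AttributionMatrix-class].
#' @return data frame with columns `feature`, `mean_abs_shap`, `rank`,
#'   ordered by decreasing importance (ties broken by name).
#' @export
summarizeImportance <- function(att) {
  M <- attributionValues(att)
  imp <- colMeans(abs(M))
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], mean_abs_shap = unname(imp[ord]),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}

#' Beeswarm-style attribution summary plot
#'
#' One row per feature (most important on top), points at the per-sample
#' Shapley values coloured by the (min-max scaled) feature value --- the
#' conventional summary view for tree-ensemble attributions.
#'
#' @param att an [AttributionMatrix-class].
#' @param X the feature matrix the attributions were computed on.
#' @param topN number of features to display.
#' @return a `ggplot` object.
#' @export
plotShapSummary <- function(att, X, topN = 10L) {
  imp <- summarizeImportance(att)
  keep <- head(imp$feature, topN)
  M <- attributionValues(att)[, keep, drop = FALSE]
  Xs <- apply(as.matrix(X)[, keep, drop = FALSE], 2L, function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  })
  df <- data.frame(
    feature = factor(rep(keep, each = nrow(M)), levels = rev(keep)),
    shap = as.vector(M),
    value = as.vector(Xs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shap, y = .data$feature,
                                   colour = .data$value)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_colour_gradient(low = "#3b4cc0", high = "#b40426",
                                   name = "feature value") +
    ggplot2::labs(x = "Shapley value (g/m2)", y = NULL)
}
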
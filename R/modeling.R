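## Stage-wise dataset splitting and the three regression models: univariate
## least squares, multiple linear regression, and a random forest tuned by a
## tree-structured Parzen estimator (TPE) over 10-fold cross-validated R2.

#' R-squared and RMSE of predictions
#'
#' `R2 = 1 - SSres/SStot`, `RMSE = sqrt(mean((pred - obs)^2))`. R2 may be
#' negative on held-out data; when the observed vector is constant R2 is
#' the undefined sentinel `NA` while RMSE is still returned.
#'
#' @param yTrue observed values.
#' @param yPred predicted values, same length.
#' @return named vector `c(r2, rmse)`.
#' @examples
#' evaluateMetrics(c(1, 2, 3), c(2, 2, 2))  # r2 = 0, rmse = sqrt(2/3)
#' @export
evaluateMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred) || length(yTrue) == 0L)
    stop("yTrue and yPred must have equal, nonzero length")
  ssRes <- sum((yPred - yTrue)^2)
  ssTot <- sum((yTrue - mean(yTrue))^2)
  r2 <- if (ssTot == 0) NA_real_ else 1 - ssRes / ssTot
  c(r2 = r2, rmse = sqrt(mean((yPred - yTrue)^2)))
}

# round-half-up, used for the training-set size so that e.g. 234 samples at
# 75% give 176 train / 58 test
roundHalfUp <- function(x) floor(x + 0.5)

#' Stage-wise train/test split
#'
#' Splits each growth stage at random into `trainFraction` training and the
#' remainder test (train size = round-half-up of `trainFraction * n`), then
#' assembles the all-stage partitions as the unions of the per-stage
#' partitions, so no sample ever sits in both train and test.
#'
#' @param featureMatrix samples x features matrix with column names.
#' @param agb aligned AGB vector (g/m2).
#' @param stage aligned vector of `"pre_heading"` / `"post_heading"`
#'   labels.
#' @param trainFraction training proportion per stage (default 0.75).
#' @param seed RNG seed controlling membership.
#' @return named list of three [StageDataset-class] objects:
#'   `pre_heading`, `post_heading`, `all_stage`, plus attribute
#'   `"trainIndex"`/`"testIndex"` on each carrying original row indices.
#' @export
splitStagewise <- function(featureMatrix, agb, stage, trainFraction = 0.75,
                           seed = 1L) {
  if (nrow(featureMatrix) != length(agb) || length(agb) != length(stage))
    stop("featureMatrix, agb and stage must be row-aligned")
  bad <- setdiff(unique(stage), c("pre_heading", "post_heading"))
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  idx <- list()
  for (s in c("pre_heading", "post_heading")) {
    rows <- which(stage == s)
    if (length(rows) < 4L)
      stop("stage ", s, " has ", length(rows), " samples; need at least 4")
    nTrain <- roundHalfUp(trainFraction * length(rows))
    tr <- sort(sample(rows, nTrain))
    idx[[s]] <- list(train = tr, test = setdiff(rows, tr))
  }
  idx$all_stage <- list(
    train = sort(c(idx$pre_heading$train, idx$post_heading$train)),
    test  = sort(c(idx$pre_heading$test, idx$post_heading$test)))
  out <- lapply(names(idx), function(s) {
    ii <- idx[[s]]
    ds <- new("StageDataset",
              stage = s,
              xTrain = featureMatrix[ii$train, , drop = FALSE],
              xTest  = featureMatrix[ii$test, , drop = FALSE],
              yTrain = agb[ii$train], yTest = agb[ii$test],
              featureNames = colnames(featureMatrix))
    attr(ds, "trainIndex") <- ii$train
    attr(ds, "testIndex") <- ii$test
    ds
  })
  names(out) <- names(idx)
  out
}

metricsFrame <- function(yTrain, predTrain, yTest = NULL, predTest = NULL) {
  m <- evaluateMetrics(yTrain, predTrain)
  df <- data.frame(partition = "train", r2 = m["r2"], rmse = m["rmse"],
                   row.names = NULL)
  if (!is.null(yTest) && length(yTest)) {
    mt <- evaluateMetrics(yTest, predTest)
    df <- rbind(df, data.frame(partition = "test", r2 = mt["r2"],
                               rmse = mt["rmse"], row.names = NULL))
  }
  df
}

#' Univariate regression of AGB on one feature
#'
#' Ordinary least squares of `agb` on a single feature, optionally with a
#' quadratic term.
#'
#' @param feature training feature vector.
#' @param agb training AGB vector.
#' @param featureTest,agbTest optional held-out partition for test metrics.
#' @param quadratic add a squared term?
#' @param name feature name recorded in the result.
#' @return a [FitResult-class] of kind `"simple"`.
#' @export
fitSimpleRegression <- function(feature, agb, featureTest = NULL,
                                agbTest = NULL, quadratic = FALSE,
                                name = "x") {
  if (length(feature) != length(agb) || length(agb) < 3L)
    stop("need aligned vectors with n >= 3")
  if (sd(feature) == 0) stop("feature has zero variance")
  X <- if (quadratic) cbind(1, feature, feature^2) else cbind(1, feature)
  fit <- lm.fit(X, agb)
  beta <- fit$coefficients
  names(beta) <- if (quadratic) c("(Intercept)", name, paste0(name, "^2"))
                 else c("(Intercept)", name)
  predf <- function(x) {
    M <- if (quadratic) cbind(1, x, x^2) else cbind(1, x)
    as.vector(M %*% beta)
  }
  new("FitResult", kind = "simple", model = predf,
      hyperparameters = list(quadratic = quadratic),
      metrics = metricsFrame(agb, predf(feature), agbTest,
                             if (!is.null(featureTest)) predf(featureTest)),
      coefficients = beta, featureNames = name, scaling = list())
}

#' Multiple linear regression
#'
#' Least-squares fit `y = X b + b0`. A rank-deficient design triggers a
#' warning and the minimum-norm solution (Moore-Penrose pseudoinverse)
#' instead of dropped coefficients.
#'
#' @param X training feature matrix (samples x features, named columns).
#' @param y training AGB vector.
#' @param xTest,yTest optional held-out partition.
#' @return a [FitResult-class] of kind `"mlr"`.
#' @export
fitMlr <- function(X, y, xTest = NULL, yTest = NULL) {
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (nrow(X) <= ncol(X))
    warning("n <= p: interpolating fit; coefficients not identifiable")
  D <- cbind(`(Intercept)` = 1, X)
  fit <- lm.fit(D, y)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    warning("rank-deficient design; returning minimum-norm solution")
    beta <- as.vector(MASS::ginv(D) %*% y)
    names(beta) <- colnames(D)
  }
  predf <- function(M) as.vector(cbind(1, M[, names(beta)[-1], drop = FALSE])
                                 %*% beta)
  new("FitResult", kind = "mlr", model = predf, hyperparameters = list(),
      metrics = metricsFrame(y, predf(X), yTest,
                             if (!is.null(xTest)) predf(xTest)),
      coefficients = beta, featureNames = colnames(X), scaling = list())
}

#' Random-forest model specification
#'
#' Hyperparameter search space and tuning budget for [fitRfTuned()].
#' Defaults: `n_estimators` 50--500, `max_depth` 3--30, `min_samples_split`
#' 2--10, `min_samples_leaf` 1--10, `max_features` from
#' \{`sqrt`, `log2`, fraction 0.3--1.0\}; 100 TPE trials scored by mean
#' 10-fold cross-validated R2.
#'
#' @param nTrials number of tuning trials.
#' @param cvFolds cross-validation folds (default 10).
#' @param seed mandatory RNG seed; the whole search is deterministic
#'   given it.
#' @param space named list of ranges: `n_estimators`, `max_depth`,
#'   `min_samples_split`, `min_samples_leaf` as `c(lo, hi)`;
#'   `max_features_frac` as `c(lo, hi)`.
#' @return a `model_spec` list.
#' @export
modelSpec <- function(nTrials = 100L, cvFolds = 10L, seed,
                      space = list(n_estimators = c(50L, 500L),
                                   max_depth = c(3L, 30L),
                                   min_samples_split = c(2L, 10L),
                                   min_samples_leaf = c(1L, 10L),
                                   max_features_frac = c(0.3, 1.0))) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(nTrials >= 1L, cvFolds >= 2L)
  structure(list(nTrials = as.integer(nTrials), cvFolds = as.integer(cvFolds),
                 seed = as.integer(seed), space = space),
            class = "model_spec")
}

# resolve the mtry count for p features under a max_features setting
resolveMtry <- function(mode, frac, p) {
  m <- switch(mode,
              sqrt = floor(sqrt(p)),
              log2 = floor(log2(p)),
              frac = round(frac * p))
  max(1L, min(p, as.integer(m)))
}

rfFit <- function(X, y, params, seed) {
  ranger::ranger(
    x = as.data.frame(X), y = y,
    num.trees = params$n_estimators,
    mtry = resolveMtry(params$max_features, params$max_features_frac,
                       ncol(X)),
    max.depth = params$max_depth,
    min.node.size = params$min_samples_split,
    min.bucket = params$min_samples_leaf,
    seed = seed, num.threads = 1L, verbose = FALSE)
}

rfCvScore <- function(X, y, params, folds, seed) {
  scores <- vapply(seq_len(max(folds)), function(k) {
    tr <- folds != k
    fit <- rfFit(X[tr, , drop = FALSE], y[tr], params, seed + k)
    pred <- predict(fit, as.data.frame(X[!tr, , drop = FALSE]),
                    num.threads = 1L)$predictions
    evaluateMetrics(y[!tr], pred)["r2"]
  }, numeric(1))
  # single-observation folds have undefined R2; score on the valid folds
  if (all(is.na(scores)))
    stop("cross-validated R2 undefined on every fold; reduce cvFolds")
  mean(scores, na.rm = TRUE)
}

# -- tree-structured Parzen estimator over the RF space ----------------------
# Independent 1-D Parzen estimators per hyperparameter: observed trials are
# split into a "good" quantile (gamma = 0.25) and the rest; candidates are
# drawn from the good-density and scored by log l(x) - log g(x) summed over
# parameters. Integers are handled on the continuous scale and rounded;
# max_features mode is categorical with Laplace-smoothed frequencies.

tpeSampleParams <- function(space) {
  ri <- function(r) sample(r[1]:r[2], 1L)
  list(n_estimators = ri(space$n_estimators),
       max_depth = ri(space$max_depth),
       min_samples_split = ri(space$min_samples_split),
       min_samples_leaf = ri(space$min_samples_leaf),
       max_features = sample(c("sqrt", "log2", "frac"), 1L),
       max_features_frac = runif(1, space$max_features_frac[1],
                                 space$max_features_frac[2]))
}

parzenLogDensity <- function(x, obs, range) {
  bw <- max(1.06 * sd(obs) * length(obs)^(-1 / 5), diff(range) / 50)
  log(rowMeans(outer(x, obs, function(a, b) dnorm(a, b, bw))) + 1e-12)
}

tpeProposal <- function(trials, scores, space, nCandidates = 24L) {
  nGood <- max(1L, ceiling(0.25 * length(scores)))
  ord <- order(scores, decreasing = TRUE)
  good <- trials[ord[seq_len(nGood)]]
  bad <- trials[ord[-seq_len(nGood)]]
  if (!length(bad)) bad <- trials

  numNames <- c("n_estimators", "max_depth", "min_samples_split",
                "min_samples_leaf", "max_features_frac")
  ranges <- list(space$n_estimators, space$max_depth,
                 space$min_samples_split, space$min_samples_leaf,
                 space$max_features_frac)
  names(ranges) <- numNames

  cand <- vector("list", nCandidates)
  score <- numeric(nCandidates)
  # draw candidates from the good kernels, score by l/g
  for (nm in numNames) {
    gObs <- vapply(good, function(t) as.numeric(t[[nm]]), numeric(1))
    bObs <- vapply(bad, function(t) as.numeric(t[[nm]]), numeric(1))
    bw <- max(1.06 * sd(gObs) * length(gObs)^(-1 / 5),
              diff(ranges[[nm]]) / 50)
    draws <- rnorm(nCandidates, sample(gObs, nCandidates, replace = TRUE), bw)
    draws <- pmin(pmax(draws, ranges[[nm]][1]), ranges[[nm]][2])
    if (nm != "max_features_frac") draws <- round(draws)
    score <- score + parzenLogDensity(draws, gObs, ranges[[nm]]) -
      parzenLogDensity(draws, bObs, ranges[[nm]])
    for (i in seq_len(nCandidates)) cand[[i]][[nm]] <- draws[i]
  }
  modes <- c("sqrt", "log2", "frac")
  gm <- vapply(good, `[[`, character(1), "max_features")
  bm <- vapply(bad, `[[`, character(1), "max_features")
  pg <- (table(factor(gm, modes)) + 1) / (length(gm) + 3)
  pb <- (table(factor(bm, modes)) + 1) / (length(bm) + 3)
  drawn <- sample(modes, nCandidates, replace = TRUE, prob = pg)
  score <- score + log(pg[drawn]) - log(pb[drawn])
  for (i in seq_len(nCandidates)) cand[[i]]$max_features <- drawn[i]

  best <- cand[[which.max(score)]]
  for (nm in setdiff(numNames, "max_features_frac"))
    best[[nm]] <- as.integer(best[[nm]])
  best
}

#' Tune and fit a random-forest AGB model
#'
#' Standardizes the inputs (z-score, parameters learned on the training
#' partition only), then runs a sequential tree-structured Parzen estimator
#' search over the spec's hyperparameter space: 10 random startup trials
#' followed by adaptive proposals, each trial scored by mean k-fold
#' cross-validated R2 on the training partition. The best configuration is
#' refit on the full training partition. The whole procedure is
#' deterministic given `spec$seed`.
#'
#' @param X training feature matrix (samples x features, named columns).
#' @param y training AGB vector.
#' @param spec a `model_spec` from [modelSpec()].
#' @param xTest,yTest optional held-out partition for test metrics.
#' @return a [FitResult-class] of kind `"rf"` whose `hyperparameters` also
#'   record the achieved CV score (`cv_r2`) and the full trial history.
#' @export
fitRfTuned <- function(X, y, spec, xTest = NULL, yTest = NULL) {
  if (!inherits(spec, "model_spec")) stop("spec must come from modelSpec()")
  if (nrow(X) < spec$cvFolds)
    stop("need at least cvFolds = ", spec$cvFolds, " training samples")
  set.seed(spec$seed)
  centre <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2L, centre, `-`), 2L, scl, `/`)

  folds <- sample(rep_len(seq_len(spec$cvFolds), nrow(Z)))
  nStartup <- min(10L, spec$nTrials)
  trials <- vector("list", spec$nTrials)
  scores <- numeric(spec$nTrials)
  for (i in seq_len(spec$nTrials)) {
    p <- if (i <= nStartup) tpeSampleParams(spec$space)
         else tpeProposal(trials[seq_len(i - 1L)], scores[seq_len(i - 1L)],
                          spec$space)
    trials[[i]] <- p
    scores[i] <- rfCvScore(Z, y, p, folds, spec$seed + i * 1000L)
  }
  best <- trials[[which.max(scores)]]
  final <- rfFit(Z, y, best, spec$seed)

  scale2 <- function(M) sweep(sweep(M[, names(centre), drop = FALSE], 2L,
                                    centre, `-`), 2L, scl, `/`)
  predTest <- if (!is.null(xTest))
    predict(final, as.data.frame(scale2(xTest)),
            num.threads = 1L)$predictions
  new("FitResult", kind = "rf", model = final,
      hyperparameters = c(best, list(cv_r2 = max(scores),
                                     n_trials = spec$nTrials,
                                     trial_scores = scores)),
      metrics = metricsFrame(y, predict(final, as.data.frame(Z),
                                        num.threads = 1L)$predictions,
                             yTest, predTest),
      coefficients = numeric(), featureNames = colnames(X),
      scaling = list(centre = centre, scale = scl))
}

#' Predict AGB from a fitted model
#'
#' Applies a [FitResult-class] of any kind to new data, reproducing the
#' training-time standardization for forests.
#'
#' @param fit a [FitResult-class].
#' @param newX matrix (or vector for `"simple"` fits) of new observations.
#' @return numeric vector of predicted AGB (g/m2).
#' @export
predictFit <- function(fit, newX) {
  switch(fit@kind,
    simple = fit@model(as.numeric(newX)),
    mlr = fit@model(as.matrix(newX)),
    rf = {
      M <- as.matrix(newX)[, names(fit@scaling$centre), drop = FALSE]
      Z <- sweep(sweep(M, 2L, fit@scaling$centre, `-`), 2L,
                 fit@scaling$scale, `/`)
      predict(fit@model, as.data.frame(Z), num.threads = 1L)$predictions
    },
    stop("unsupported model kind: ", fit@kind))
}
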
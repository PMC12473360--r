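# Stage-wise splitting, the three regression models, and metric identities.

dummyFeatures <- function(n, p = 3L, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
}

test_that("stage-wise split sizes follow round-half-up at 75%", {
  n <- 468L + 234L
  X <- dummyFeatures(n)
  stage <- rep(c("pre_heading", "post_heading"), c(468L, 234L))
  agb <- runif(n, 200, 1900)
  sp <- splitStagewise(X, agb, stage, seed = 5L)
  expect_equal(nrow(trainX(sp$pre_heading)), 351L)
  expect_equal(nrow(testX(sp$pre_heading)), 117L)
  expect_equal(nrow(trainX(sp$post_heading)), 176L)   # 175.5 rounds up
  expect_equal(nrow(testX(sp$post_heading)), 58L)
  expect_equal(nrow(trainX(sp$all_stage)), 527L)
  expect_equal(nrow(testX(sp$all_stage)), 175L)
})

test_that("split partitions are disjoint, exhaustive and seed-reproducible", {
  X <- dummyFeatures(40L)
  stage <- rep(c("pre_heading", "post_heading"), c(24L, 16L))
  agb <- runif(40, 100, 500)
  a <- splitStagewise(X, agb, stage, seed = 9L)
  b <- splitStagewise(X, agb, stage, seed = 9L)
  for (s in names(a)) {
    expect_identical(attr(a[[s]], "trainIndex"), attr(b[[s]], "trainIndex"))
    expect_length(intersect(attr(a[[s]], "trainIndex"),
                            attr(a[[s]], "testIndex")), 0L)
  }
  expect_setequal(c(attr(a$all_stage, "trainIndex"),
                    attr(a$all_stage, "testIndex")), 1:40)
  expect_setequal(attr(a$all_stage, "trainIndex"),
                  c(attr(a$pre_heading, "trainIndex"),
                    attr(a$post_heading, "trainIndex")))
  expect_error(splitStagewise(X, agb, rep("pre_heading", 40L)), "unknown|at least")
  expect_error(splitStagewise(X[1:6, ], agb[1:6],
                              c(rep("pre_heading", 3), rep("post_heading", 3))),
               "at least 4")
})

test_that("R2/RMSE identities hold", {
  y <- c(1, 2, 3)
  expect_equal(evaluateMetrics(y, y), c(r2 = 1, rmse = 0))
  expect_equal(evaluateMetrics(y, rep(mean(y), 3))[["r2"]], 0)
  m <- evaluateMetrics(y, c(2, 2, 2))
  expect_equal(m[["r2"]], 0)
  expect_equal(m[["rmse"]], sqrt(2 / 3))
  mc <- evaluateMetrics(rep(5, 4), c(4, 5, 6, 5))
  expect_true(is.na(mc[["r2"]]))
  expect_equal(mc[["rmse"]], sqrt(mean(c(1, 0, 1, 0))))
  expect_error(evaluateMetrics(1:3, 1:4), "equal")
})

test_that("simple regression recovers exact lines and matches the oracle", {
  x <- c(0.1, 0.4, 0.7, 1.2, 1.9)
  fit <- fitSimpleRegression(x, 2 * x + 1, name = "ndvi")
  expect_equal(unname(fitCoefficients(fit)), c(1, 2), tolerance = 1e-10)
  m <- fitMetrics(fit)
  expect_equal(m$r2[m$partition == "train"], 1)
  expect_equal(m$rmse[m$partition == "train"], 0, tolerance = 1e-8)
  # response unrelated to x: training R2 = 0 for a constant response
  expect_true(is.na(fitMetrics(
    fitSimpleRegression(x, rep(3, 5)))$r2[1]))
  expect_error(fitSimpleRegression(rep(1, 5), 1:5), "zero variance")
  set.seed(20)
  x2 <- rnorm(12); y2 <- 3 * x2 + rnorm(12)
  f2 <- fitSimpleRegression(x2, y2)
  expect_equal(unname(fitCoefficients(f2)),
               unname(normalEquationsOracle(cbind(x2), y2)),
               tolerance = 1e-8)
  # quadratic flag fits a parabola exactly
  f3 <- fitSimpleRegression(x2, 1 + x2 - 2 * x2^2, quadratic = TRUE)
  expect_equal(unname(fitCoefficients(f3)), c(1, 1, -2), tolerance = 1e-8)
})

test_that("MLR matches the normal equations and never loses training R2", {
  set.seed(21)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(2, -1, 0.5)
  yExact <- X %*% beta + 4
  fit <- fitMlr(X, as.vector(yExact))
  expect_equal(unname(fitCoefficients(fit)), c(4, beta), tolerance = 1e-8)
  expect_equal(fitMetrics(fit)$r2[1], 1)
  y <- as.vector(yExact) + rnorm(20)
  f1 <- fitMlr(X, y)
  expect_equal(unname(fitCoefficients(f1)),
               unname(normalEquationsOracle(X, y)), tolerance = 1e-8)
  # a pure-noise column cannot decrease training R2 (nested least squares)
  Xplus <- cbind(X, noise = rnorm(20))
  f2 <- fitMlr(Xplus, y)
  expect_gte(fitMetrics(f2)$r2[1], fitMetrics(f1)$r2[1] - 1e-12)
  # duplicated column: rank-deficient -> warning + minimum-norm solution
  Xdup <- cbind(X, a2 = X[, "a"])
  expect_warning(f3 <- fitMlr(Xdup, y), "minimum-norm|rank")
  expect_equal(predictFit(f3, Xdup), predictFit(f1, X), tolerance = 1e-6)
})

test_that("tuned forests are deterministic and bounded by the training range", {
  set.seed(30)
  n <- 80L
  X <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("u", "v", "w")))
  y <- 500 + 400 * sin(2 * X[, 1]) + 200 * X[, 2]^2 + rnorm(n, 0, 30)
  spec <- modelSpec(nTrials = 4L, cvFolds = 4L, seed = 11L)
  f1 <- fitRfTuned(X, y, spec)
  f2 <- fitRfTuned(X, y, spec)
  expect_identical(fitHyperparameters(f1)[c("n_estimators", "max_depth",
                                            "max_features")],
                   fitHyperparameters(f2)[c("n_estimators", "max_depth",
                                            "max_features")])
  newX <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("u", "v", "w")))
  expect_identical(predictFit(f1, newX), predictFit(f2, newX))
  preds <- predictFit(f1, newX)
  expect_true(all(preds >= min(y) & preds <= max(y)))
  # the chosen configuration achieves the best evaluated CV score
  hp <- fitHyperparameters(f1)
  expect_equal(hp$cv_r2, max(hp$trial_scores))
  expect_error(modelSpec(nTrials = 5L), "seed")
  expect_error(fitRfTuned(X[1:5, ], y[1:5],
                          modelSpec(nTrials = 2L, cvFolds = 10L, seed = 1L)),
               "at least")
})

test_that("tuning does not underperform default forests on nonlinear data", {
  deficits <- vapply(1:5, function(s) {
    set.seed(100 + s)
    n <- 300L
    X <- matrix(runif(n * 4), n, 4,
                dimnames = list(NULL, paste0("x", 1:4)))
    y <- 600 * plogis(6 * (X[, 1] - 0.5)) + 300 * X[, 2] * X[, 3] +
      rnorm(n, 0, 40)
    tr <- 1:225; te <- 226:300
    tuned <- fitRfTuned(X[tr, ], y[tr],
                        modelSpec(nTrials = 10L, cvFolds = 5L,
                                  seed = 100 + s),
                        X[te, ], y[te])
    default <- ranger::ranger(x = as.data.frame(X[tr, ]), y = y[tr],
                              seed = 100 + s, num.threads = 1L)
    defPred <- predict(default, as.data.frame(X[te, ]),
                       num.threads = 1L)$predictions
    mt <- fitMetrics(tuned)
    mt$r2[mt$partition == "test"] - evaluateMetrics(y[te], defPred)[["r2"]]
  }, numeric(1))
  expect_true(all(deficits >= -0.02))
})
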
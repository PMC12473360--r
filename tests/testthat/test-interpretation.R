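# Shapley attributions: local accuracy, coalition-lattice correctness on
# tiny models, standardization and importance ranking.

test_that("constant and single-feature models attribute trivially", {
  X <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  constModel <- function(M) rep(7, nrow(M))
  att <- shapleyAttributions(constModel, X)
  expect_equal(unname(attributionValues(att)),
               matrix(0, 10, 2), tolerance = 1e-12)
  expect_equal(attributionBase(att), 7)
  oneFeat <- function(M) 3 * M[, "a"]
  att2 <- shapleyAttributions(oneFeat, X)
  expect_equal(unname(attributionValues(att2)[, "b"]), rep(0, 10),
               tolerance = 1e-12)
  expect_false(all(attributionValues(att2)[, "a"] == 0))
})

test_that("a two-feature stump matches brute-force coalition enumeration", {
  # stump: predict 100 when a > 0.5 else 40, ignoring b
  stump <- function(M) ifelse(M[, "a"] > 0.5, 100, 40)
  X <- matrix(c(0.9, 0.2, 0.3, 0.8), 2, 2,
              dimnames = list(NULL, c("a", "b")))
  bg <- matrix(runif(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  att <- shapleyAttributions(stump, X, bg)
  # independent oracle: enumerate the 2-player lattice directly
  for (r in 1:2) {
    x <- X[r, ]
    v <- function(S) {   # S: character subset of features
      H <- bg
      for (f in S) H[, f] <- x[f]
      mean(stump(H))
    }
    phiA <- 0.5 * ((v("a") - v(character(0))) + (v(c("a", "b")) - v("b")))
    phiB <- 0.5 * ((v("b") - v(character(0))) + (v(c("a", "b")) - v("a")))
    expect_equal(unname(attributionValues(att)[r, "a"]), phiA,
                 tolerance = 1e-10)
    expect_equal(unname(attributionValues(att)[r, "b"]), phiB,
                 tolerance = 1e-10)
  }
})

test_that("local accuracy holds for a tuned forest", {
  set.seed(41)
  n <- 60L
  X <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 300 * X[, 1] + 200 * X[, 2]^2 + rnorm(n, 0, 10)
  fit <- fitRfTuned(X, y, modelSpec(nTrials = 3L, cvFolds = 4L, seed = 2L))
  att <- shapleyAttributions(fit, X[1:10, ], X)
  recon <- attributionBase(att) + rowSums(attributionValues(att))
  expect_equal(recon, predictFit(fit, X[1:10, ]), tolerance = 1e-6)
  expect_error(shapleyAttributions(42, X), "unsupported")
})

test_that("the sampling fallback also satisfies local accuracy", {
  set.seed(55)
  p <- 17L   # above the exact-enumeration cutoff
  X <- matrix(runif(5 * p), 5, p, dimnames = list(NULL, paste0("g", 1:p)))
  beta <- rnorm(p)
  lin <- function(M) as.vector(M %*% beta) + 2
  att <- shapleyAttributions(lin, X, nPermutations = 64L, seed = 3L)
  recon <- attributionBase(att) + rowSums(attributionValues(att))
  expect_equal(recon, lin(X), tolerance = 1e-8)
  att2 <- shapleyAttributions(lin, X, nPermutations = 64L, seed = 3L)
  expect_identical(attributionValues(att), attributionValues(att2))
})

test_that("functionally interchangeable features earn equal attribution", {
  # f(M) = m1 + m2 with an exchangeable background (identical marginals):
  # the two features are then fully interchangeable players
  add <- function(M) M[, 1] + M[, 2]
  set.seed(13)
  bgv <- rnorm(20)
  bg <- cbind(p = bgv, q = rev(bgv))
  X <- matrix(c(1.5, 1.5), 1, 2, dimnames = list(NULL, c("p", "q")))
  att <- shapleyAttributions(add, X, bg)
  expect_equal(unname(attributionValues(att)[1, "p"]),
               unname(attributionValues(att)[1, "q"]), tolerance = 1e-10)
})

test_that("Z-score standardization uses population moments", {
  M <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(Z <- standardizeAttributions(M), "constant")
  expect_equal(Z[, "a"], c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(unname(Z[, "a"]), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  expect_equal(Z[, "b"], c(0, 0, 0))
  # idempotence on already standardized input
  Z2 <- standardizeAttributions(cbind(a = Z[, "a"]))
  expect_equal(Z2[, "a"], Z[, "a"], tolerance = 1e-9)
  expect_error(standardizeAttributions(M[1, , drop = FALSE]), "at least 2")
})

test_that("importance ranking follows mean |attribution| and ignores order", {
  f <- function(M) 10 * M[, "f1"] + 0 * M[, "f2"]
  set.seed(9)
  X <- matrix(runif(30), 15, 2, dimnames = list(NULL, c("f1", "f2")))
  att <- shapleyAttributions(f, X)
  imp <- summarizeImportance(att)
  expect_equal(imp$feature[1], "f1")
  attPerm <- shapleyAttributions(f, X[sample(15), ])
  expect_identical(summarizeImportance(attPerm)$feature, imp$feature)
  pl <- plotShapSummary(att, X)
  expect_s3_class(pl, "ggplot")
})
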
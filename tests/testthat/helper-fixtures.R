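# Shared fixtures, all generated in code.

# canonical band-mean vector for index tests
meansFixture <- function(green = 0.12, red = 0.08, red_edge = 0.28,
                         nir = 0.46) {
  c(green = green, red = red, red_edge = red_edge, nir = nir)
}

# a small two-stage synthetic sample set for pipeline-level tests
smallSampleSet <- function(nPre = 24L, nPost = 16L, seedPre = 301L,
                           seedPost = 302L, patchSize = 16L) {
  c(generateDataset(sceneConfig("pre_heading", seed = seedPre,
                                patchSize = patchSize), n = nPre),
    generateDataset(sceneConfig("post_heading", seed = seedPost,
                                patchSize = patchSize), n = nPost))
}

# independent rank-then-Pearson oracle for Spearman checks
spearmanOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# least-squares by explicit normal equations (oracle for lm-based fits)
normalEquationsOracle <- function(X, y) {
  D <- cbind(1, X)
  solve(t(D) %*% D, t(D) %*% y)[, 1]
}
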
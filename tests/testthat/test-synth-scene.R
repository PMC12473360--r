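# Synthetic canopy-scene generator: determinism, spectral/textural links to
# the latent biomass, saturation, and the panicle-speckle effect.

test_that("configuration invariants are enforced", {
  expect_error(sceneConfig("pre_heading", patchSize = 7L), "even")
  expect_error(sceneConfig("pre_heading", patchSize = 6L), ">= 8")
  expect_error(sceneConfig("pre_heading", agbRange = c(500, 100)),
               "increasing")
  expect_error(sceneConfig("pre_heading", coverageGain = 0), "positive")
  expect_s4_class(sceneConfig("post_heading"), "SceneConfig")
})

test_that("sampling outside the configured AGB range is a domain error", {
  cfg <- sceneConfig("pre_heading")
  expect_error(generateSample(cfg, 50), "outside")
  expect_error(generateSample(cfg, 5000), "outside")
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- sceneConfig("post_heading", seed = 17L)
  a <- generateDataset(cfg, n = 4L)
  b <- generateDataset(cfg, n = 4L)
  expect_identical(a, b)
  cfg2 <- sceneConfig("post_heading", seed = 18L)
  c <- generateDataset(cfg2, n = 4L)
  expect_false(identical(a[[1]]$patches$nir, c[[1]]$patches$nir))
})

test_that("a minimum-AGB noise-free patch is nearly bare soil", {
  cfg <- sceneConfig("pre_heading", noiseSd = 0, reflJitterSd = 0,
                     seed = 2L)
  agbMin <- cfg@agbRange[1]
  # expectation derived from the generator's own constants:
  # cover = 1 - exp(-gain * agb); band mean = cover*canopy + (1-cover)*soil
  cover <- 1 - exp(-cfg@coverageGain * agbMin)
  expect_lt(cover, 0.2)
  nirExp <- cover * cfg@canopyRefl[["nir"]] + (1 - cover) * cfg@soilRefl[["nir"]]
  redExp <- cover * cfg@canopyRefl[["red"]] + (1 - cover) * cfg@soilRefl[["red"]]
  expect_lt((nirExp - redExp) / (nirExp + redExp), 0.2)
  # a single patch has few independent canopy blobs, so average the ROI
  # NDVI over repeated draws before comparing with the derived expectation
  set.seed(2L)
  ndvi <- replicate(30, {
    s <- generateSample(cfg, agbMin)
    nir <- roiMeanReflectance(s$patches$nir)
    red <- roiMeanReflectance(s$patches$red)
    (nir - red) / (nir + red)
  })
  expect_lt(mean(ndvi), 0.2)
  # soil pixels: NIR close to red by construction
  expect_lt(abs(cfg@soilRefl[["nir"]] - cfg@soilRefl[["red"]]), 0.05)
  s <- generateSample(cfg, agbMin)
  expect_true(all(vapply(s$patches, function(p) all(p >= 0), logical(1))))
})

test_that("default layout yields one sample per plot (18-plot grid)", {
  ds <- generateDataset(sceneConfig("pre_heading", seed = 4L))
  expect_length(ds, 18L)
  expect_identical(vapply(ds, `[[`, character(1), "stage"),
                   rep("pre_heading", 18L))
  expect_false(anyDuplicated(vapply(ds, `[[`, character(1),
                                    "plot_id")) > 0)
})

test_that("mean NDVI and LL-NIR energy increase monotonically with AGB", {
  ds <- generateDataset(sceneConfig("pre_heading", seed = 7L), n = 200L)
  agb <- vapply(ds, `[[`, numeric(1), "agb")
  ndvi <- vapply(ds, function(s) {
    nir <- mean(s$patches$nir); red <- mean(s$patches$red)
    (nir - red) / (nir + red)
  }, numeric(1))
  llEne <- vapply(ds, function(s)
    subbandStats(haarDwt2(s$patches$nir)$LL)[["Ene"]], numeric(1))
  expect_gt(spearmanRho(agb, ndvi), 0.9)
  expect_gt(spearmanRho(agb, llEne), 0.8)
})

test_that("NDVI saturates: narrower spread over the top AGB quartile", {
  cfg <- sceneConfig("post_heading", noiseSd = 0, reflJitterSd = 0,
                     seed = 9L)
  ds <- generateDataset(cfg, n = 200L)
  agb <- vapply(ds, `[[`, numeric(1), "agb")
  ndvi <- vapply(ds, function(s) {
    nir <- mean(s$patches$nir); red <- mean(s$patches$red)
    (nir - red) / (nir + red)
  }, numeric(1))
  lo <- agb <= quantile(agb, 0.25)
  hi <- agb >= quantile(agb, 0.75)
  expect_lt(diff(range(ndvi[hi])), diff(range(ndvi[lo])))
})

test_that("seed changes the patches but not the AGB distribution", {
  c1 <- sceneConfig("pre_heading", seed = 21L)
  c2 <- sceneConfig("pre_heading", seed = 22L)
  d1 <- generateDataset(c1, n = 150L)
  d2 <- generateDataset(c2, n = 150L)
  a1 <- vapply(d1, `[[`, numeric(1), "agb")
  a2 <- vapply(d2, `[[`, numeric(1), "agb")
  expect_false(identical(d1[[1]]$patches$red, d2[[1]]$patches$red))
  ks <- suppressWarnings(stats::ks.test(a1, a2))
  expect_gt(ks$p.value, 0.001)   # equality-of-distribution at the 0.1% level
})

test_that("speckle-free pre-heading detail variance sits near the noise floor", {
  # the smooth canopy/soil field contributes about one noise variance of
  # high-frequency energy (derived from the field's 9x9 smoothing kernel),
  # so total HH variance stays below 3 * noiseSd^2
  cfg <- sceneConfig("pre_heading", seed = 31L)
  ds <- generateDataset(cfg, n = 30L)
  hhVar <- vapply(ds, function(s)
    subbandStats(haarDwt2(s$patches$nir)$HH)[["Var"]], numeric(1))
  expect_true(all(hhVar < 3 * cfg@noiseSd^2))
})

test_that("panicle speckle strictly raises mean HH variance (paired seeds)", {
  diffs <- vapply(1:50, function(s) {
    cfgOn <- sceneConfig("post_heading", seed = s)
    cfgOff <- sceneConfig("post_heading", speckleDensity = 0, seed = s)
    agb <- 1200
    set.seed(s); on <- generateSample(cfgOn, agb)
    set.seed(s); off <- generateSample(cfgOff, agb)
    subbandStats(haarDwt2(on$patches$nir)$HH)[["Var"]] -
      subbandStats(haarDwt2(off$patches$nir)$HH)[["Var"]]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_lt(stats::wilcox.test(diffs, alternative = "greater")$p.value, 0.001)
  # and density scales the effect: more speckle never less HH variance
  dens <- c(0.002, 0.01, 0.03)
  hh <- vapply(dens, function(d) {
    cfg <- sceneConfig("post_heading", speckleDensity = d, seed = 77L)
    mean(vapply(generateDataset(cfg, n = 10L), function(s)
      subbandStats(haarDwt2(s$patches$nir)$HH)[["Var"]], numeric(1)))
  }, numeric(1))
  expect_true(all(diff(hh) > 0))
})

test_that("written datasets round-trip through the file interface", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(sceneConfig("pre_heading", seed = 41L,
                                    patchSize = 12L), n = 3L)
  gt <- writeDataset(ds, dir)
  expect_setequal(gt$plot_id, vapply(ds, `[[`, character(1), "plot_id"))
  img <- readMultibandTiff(file.path(dir, paste0(ds[[1]]$plot_id, ".tif")))
  expect_equal(imageBands(img)$nir, ds[[1]]$patches$nir, tolerance = 1e-6)
})
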
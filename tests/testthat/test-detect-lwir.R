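test_that("morphological background: relief is small on smooth scenes,\n          recovers hills, and is never negative", {
  h <- 120; w <- 160
  px <- matrix(rep(0:(w - 1), each = h), h, w)
  smooth <- 26 + 2 * sin(px / 60)            # large-scale-only structure
  dec <- morphologicalBackground(smooth, seRadius = 12)
  expect_lt(max(dec$relief), 0.05)
  expect_true(all(dec$relief >= 0))
  # single Gaussian hill on a flat 28 degC field
  tm <- addHill(matrix(28, h, w), 80, 60, amp = 3, sigma = 4)
  dec2 <- morphologicalBackground(tm, seRadius = 12)
  expect_gt(max(dec2$relief), 2.8)
  expect_lt(abs(dec2$background[61, 81] - 28), 0.1)
  expect_true(all(dec2$relief >= -1e-12))
})

test_that("threshold and cleaning: dTmin, area opening, hole filling", {
  cfg <- lwirDetectConfig()
  # everything below the 2 degC threshold -> empty mask
  expect_false(any(thresholdAndClean(matrix(1.9, 60, 80), cfg)))
  # scattered speckles below the 20 px area floor are removed
  sp <- matrix(0, 60, 80)
  set.seed(3)
  sp[cbind(sample(60, 10), sample(80, 10))] <- 5
  expect_false(any(thresholdAndClean(sp, cfg)))
  # an annulus becomes a solid disk after hole filling
  h <- 60; w <- 80
  px <- matrix(rep(0:(w - 1), each = h), h, w)
  py <- matrix(rep(0:(h - 1), times = w), h, w)
  rr <- sqrt((px - 40)^2 + (py - 30)^2)
  ann <- 3 * (rr >= 4 & rr <= 7)
  mask <- thresholdAndClean(ann, cfg)
  expect_true(mask[31, 41])    # the hole got filled
})

test_that("component filter: area bounds, circularity, peak relief", {
  cfg <- lwirDetectConfig()
  # the stated defaults yield these derived area bounds
  expect_equal(cfg$Amin, 0.4 * pi * 25, tolerance = 1e-12)
  expect_equal(cfg$Amax, 2.5 * pi * 7.5^2, tolerance = 1e-12)
  expect_equal(round(cfg$Amin, 1), 31.4)
  expect_equal(round(cfg$Amax, 1), 441.8)
  # an elongated 3 x 60 warm streak is rejected by circularity
  relief <- matrix(0, 120, 160)
  relief[60:62, 40:99] <- 3
  mask <- relief >= cfg$dTmin
  expect_length(filterComponents(mask, relief, cfg), 0)
  # a compact hill passes
  relief2 <- addHill(matrix(0, 120, 160), 80, 60, amp = 4, sigma = 4.5)
  mask2 <- thresholdAndClean(relief2, cfg)
  comps <- filterComponents(mask2, relief2, cfg)
  expect_length(comps, 1)
  expect_gt(comps[[1]]$circularity, cfg$tauCirc)
  # a low hill that survives the mask via closing is dropped by the
  # component-level peak-relief condition
  reliefLow <- addHill(matrix(0, 120, 160), 80, 60, amp = 4, sigma = 4.5)
  maskLow <- thresholdAndClean(reliefLow, cfg)
  expect_length(filterComponents(maskLow, reliefLow * 0.35, cfg), 0)
})

test_that("weighted barycentre: symmetry, hand arithmetic, fallback", {
  # symmetric hill at a sub-pixel position
  relief <- addHill(matrix(0, 80, 100), 30.5, 40.5, amp = 4, sigma = 4)
  comp <- relief >= 1
  bc <- weightedBarycenter(comp, relief)
  expect_lt(abs(bc["x"] - 30.5), 0.1)
  expect_lt(abs(bc["y"] - 40.5), 0.1)
  # two-pixel hand computation: x = {10, 11}, weights {1, 3}
  comp2 <- matrix(FALSE, 5, 15)
  comp2[3, 11:12] <- TRUE          # 0-based x = 10, 11
  w2 <- matrix(0, 5, 15); w2[3, 11] <- 1; w2[3, 12] <- 3
  bc2 <- weightedBarycenter(comp2, w2)
  expect_equal(unname(bc2["x"]), 10.75)
  # all-zero weights: warning + unweighted centroid
  expect_warning(bc3 <- weightedBarycenter(comp2, w2 * 0), "unweighted")
  expect_equal(unname(bc3["x"]), 10.5)
  # anisotropic damping moves the barycentre by less than a pixel
  aniso <- relief
  px <- matrix(rep(0:99, each = 80), 80, 100)
  aniso[px > 30.5] <- aniso[px > 30.5] * 0.7
  bc4 <- weightedBarycenter(aniso >= 1, aniso)
  expect_lt(abs(bc4["x"] - 30.5), 1)
})

test_that("thermal-hill detector: full fixture, gradient invariance, empty", {
  set.seed(41)
  h <- 120; w <- 160
  truth <- cbind(c(20, 20, 20, 20, 140, 140, 140, 140) + runif(8, -3, 3),
                 rep(c(20, 46, 72, 98), 2) + runif(8, -3, 3))
  base <- matrix(28, h, w)
  px <- matrix(rep(0:(w - 1), each = h), h, w)
  base <- base + 3 * exp(-((px - 80)^2) / (2 * 25^2))  # broad warm middle
  tm <- base
  amps <- runif(8, 3, 6)
  for (i in 1:8) tm <- addHill(tm, truth[i, 1], truth[i, 2], amps[i], 4.5)
  det <- detectLwirMarkers(tm)
  expect_equal(nrow(det), 8)
  expect_lt(max(nearestDist(as.matrix(det[, c("x", "y")]), truth)), 0.5)
  expect_true(all(det$modality == "LWIR"))
  # additive constant and a global 2 degC/image-width gradient change
  # nothing material
  grad <- matrix(rep(seq(0, 2, length.out = w), each = h), h, w)
  det2 <- detectLwirMarkers(tm + 1.5 + grad)
  expect_equal(nrow(det2), 8)
  expect_lt(max(nearestDist(as.matrix(det2[, c("x", "y")]),
                            as.matrix(det[, c("x", "y")]))), 0.2)
  # centres lie inside their component bounding boxes
  dec <- morphologicalBackground(tm, lwirDetectConfig()$seRadius)
  comps <- filterComponents(thresholdAndClean(dec$relief),
                            dec$relief)
  for (co in comps) {
    bc <- weightedBarycenter(co$pixels, dec$relief)
    expect_gte(bc["x"], co$bbox["xmin"]); expect_lte(bc["x"], co$bbox["xmax"])
    expect_gte(bc["y"], co$bbox["ymin"]); expect_lte(bc["y"], co$bbox["ymax"])
  }
  # empty scene
  expect_equal(nrow(detectLwirMarkers(matrix(27, h, w))), 0)
})
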
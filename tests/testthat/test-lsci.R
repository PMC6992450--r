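# Spatial contrast, BFI and relative CBF.

test_that("contrast of a constant frame is zero and of a checkerboard ~1", {
  expect_true(all(contrastValues(spatialContrast(matrix(5, 32, 32))) == 0))
  # 7x7 patch of {0, 2} checkerboard: mean ~1, population sd ~1 -> K ~ 1
  cb <- outer(1:32, 1:32, function(i, j) 2 * ((i + j) %% 2))
  K <- contrastValues(spatialContrast(cb, window = 7L))
  # hand value: the window at (16,16) holds 25 zeros and 24 twos
  # (the center cell is 0); sample-sd convention over the 49 values
  mu <- 48 / 49
  s <- sqrt((25 * mu^2 + 24 * (2 - mu)^2) / 48)
  expect_equal(K[16, 16], s / mu, tolerance = 1e-12)
  expect_equal(K[16, 16], 1, tolerance = 0.05)
})

test_that("contrast is invariant to intensity scaling", {
  set.seed(5)
  fr <- matrix(rexp(64^2), 64)
  k1 <- contrastValues(spatialContrast(fr))
  k2 <- contrastValues(spatialContrast(fr * 37.5))
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("border policies behave as declared", {
  set.seed(1)
  fr <- matrix(rexp(30 * 40), 30, 40)
  kr <- contrastValues(spatialContrast(fr, border = "reflect"))
  km <- contrastValues(spatialContrast(fr, border = "mask"))
  expect_identical(dim(kr), dim(fr))
  expect_true(all(is.na(km[1:3, ])) && all(is.na(km[, 1:3])))
  # interior agrees between policies
  expect_equal(kr[10:20, 10:20], km[10:20, 10:20])
  expect_error(spatialContrast(matrix(1, 5, 5), window = 7L), "larger")
})

test_that("BFI arithmetic and contrast-floor masking", {
  cm <- new("ContrastMap", K = array(c(1, 0.5, 0, NA), c(2, 2, 1)),
            window = 7L)
  b <- bfiValues(bloodFlowIndex(cm, k_floor = 1e-3))
  expect_equal(b[1, 1, 1], 1)
  expect_equal(b[2, 1, 1], 4)
  expect_true(is.na(b[1, 2, 1]))  # K = 0 masked, not infinite
  expect_true(is.na(b[2, 2, 1]))
})

test_that("BFI ratio of two flow states matches the K(x) oracle", {
  # tau and 5*tau at exposure >> tau: ROI-mean BFI ratio ~ 1/5
  st_base <- genSpeckleStack(uniform_phantom(128L, 20e-6), n_frames = 10L,
                             seed = 21L)
  st_occl <- genSpeckleStack(uniform_phantom(128L, 100e-6), n_frames = 10L,
                             seed = 22L)
  mb <- function(st) mean(bfiValues(bloodFlowIndex(spatialContrast(st))),
                          na.rm = TRUE)
  ratio <- mb(st_occl) / mb(st_base)
  k2 <- function(x) speckleContrastTheory(x)^2
  expect_equal(ratio, k2(250) / k2(50), tolerance = 0.02)
})

test_that("relative CBF of the baseline against itself is exactly 100%", {
  st <- genSpeckleStack(uniform_phantom(48L), n_frames = 6L, seed = 3L)
  roi <- list(all = matrix(TRUE, 48, 48))
  r <- relativeCBF(st, baseline_frames = 1:6, rois = roi, smooth_s = 0)
  expect_equal(mean(r$percent_map), 100, tolerance = 1e-9)
  # each frame's trace is its own BFI over the 6-frame mean: near 100
  expect_equal(mean(r$traces$percent_baseline), 100, tolerance = 1e-9)
})

test_that("gap intervals yield explicit missing values, not interpolation", {
  st <- genSpeckleStack(uniform_phantom(48L), n_frames = 20L, fps = 10,
                        exposure_s = 0.005, seed = 4L)
  r <- relativeCBF(st, 1:5, list(all = matrix(TRUE, 48, 48)),
                   gaps = list(c(0.95, 1.25)))
  tr <- r$traces
  expect_true(all(is.na(tr$percent_baseline[tr$t_s >= 0.95 & tr$t_s <= 1.25])))
  expect_true(all(!is.na(tr$percent_baseline[tr$t_s < 0.9])))
  expect_error(relativeCBF(st, integer(), list(all = matrix(TRUE, 48, 48))),
               "baseline")
})

test_that("synthetic occlusion recovers the generator tau ratio end to end", {
  res <- simulateOcclusionDrop(shape = c(128L, 128L), n_frames = 30L,
                               seed = 11L)
  expect_equal(res$vessel_drop_pct, res$vessel_drop_theory, tolerance = 0.02)
  expect_equal(res$core_drop_pct, res$core_drop_theory, tolerance = 0.02)
})
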
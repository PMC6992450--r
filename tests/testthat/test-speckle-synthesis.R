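# Speckle generator: statistical fidelity to the closed-form K(x, beta),
# determinism, and contract errors.

test_that("closed-form contrast has the right limits and series continuity", {
  # x -> 0: fully developed static speckle, K -> sqrt(beta)
  expect_equal(speckleContrastTheory(0), 1)
  expect_equal(speckleContrastTheory(0, beta = 0.64), 0.8)
  # series branch joins the exact expression smoothly at the switch point
  expect_equal(speckleContrastTheory(9.9e-5), speckleContrastTheory(1.01e-4),
               tolerance = 1e-6)
  # exact hand evaluation at x = 1: K^2 = (e^-2 + 1) / 2
  expect_equal(speckleContrastTheory(1)^2, (exp(-2) + 1) / 2)
  # monotone decreasing in x
  k <- speckleContrastTheory(c(0.1, 1, 10, 100))
  expect_true(all(diff(k) < 0))
})

test_that("closed-form BFI drops for the protocol tau ratios are ~80% and ~60%", {
  # evaluate K(x) at x = 250 and x = 50 (and 100) before trusting simulation
  k2 <- function(x) (exp(-2 * x) - 1 + 2 * x) / (2 * x^2)
  expect_equal(bfiDropTheory(20e-6, 100e-6, 0.005),
               100 * (1 - k2(250) / k2(50)))
  expect_equal(bfiDropTheory(20e-6, 100e-6, 0.005), 79.84, tolerance = 1e-3)
  expect_equal(bfiDropTheory(20e-6, 50e-6, 0.005), 59.88, tolerance = 1e-3)
})

test_that("empirical patch contrast matches theory within 2% across x regimes", {
  for (x in c(0.1, 1, 10, 100)) {
    ph <- uniform_phantom(n = 128L, tau = 0.004 / x)  # 4-ms exposure below
    st <- genSpeckleStack(ph, exposure_s = 0.004, n_frames = 1L, seed = 42L)
    fr <- frames(st)[, , 1]
    emp <- sd(fr) / mean(fr)   # one homogeneous 1.6e4-px patch
    expect_lt(abs(emp - speckleContrastTheory(x)) / speckleContrastTheory(x),
              0.02)
  }
})

test_that("static scatterers give fully developed speckle with K near 1", {
  ph <- uniform_phantom(n = 128L, tau = 1e6)   # tau -> Inf
  st <- genSpeckleStack(ph, exposure_s = 0.004, n_frames = 1L, seed = 7L)
  fr <- frames(st)[, , 1]
  expect_equal(sd(fr) / mean(fr), 1, tolerance = 0.02)
  # the 49-sample window estimator of K carries a known O(1/n) downward
  # bias (~2% for exponential intensities), hence the looser band here
  km <- contrastValues(spatialContrast(st))
  expect_equal(mean(km), 1, tolerance = 0.035)
})

test_that("speckle disabled yields uniform frames with zero contrast", {
  st <- genSpeckleStack(uniform_phantom(32L), n_frames = 2L, speckle = FALSE)
  expect_true(all(frames(st) == 1000))
  expect_true(all(contrastValues(spatialContrast(st)) == 0))
})

test_that("generators are pure functions of (spec, seed)", {
  ph <- makeStrokePhantom(c(48L, 48L), vessel_tau_factor = 5)
  a <- genSpeckleStack(ph, n_frames = 3L, seed = 123L)
  b <- genSpeckleStack(ph, n_frames = 3L, seed = 123L)
  expect_identical(frames(a), frames(b))
  c <- genSpeckleStack(ph, n_frames = 3L, seed = 124L)
  expect_false(identical(frames(a), frames(c)))
})

test_that("invalid speckle specs are rejected", {
  expect_error(FlowPhantom(matrix(c(1e-5, -1e-5), 2, 2)), "positive")
  # exposure longer than the frame interval
  expect_error(genSpeckleStack(uniform_phantom(32L), exposure_s = 0.030,
                               fps = 40), "frame interval")
})
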
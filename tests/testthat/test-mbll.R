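# Modified Beer-Lambert chain: forward/inverse consistency and block design.

test_that("dOD identities hold", {
  sp <- hemoForwardSpec(dHbO_t = numeric(300), dHbR_t = numeric(300),
                        spatial_kernel = matrix(1, 4, 4), n_trials = 1)
  mv <- genMultispectralMovie(sp)
  # zero absorption change: I = I0 exactly, dOD = 0
  expect_true(all(frames(mv) == 1000))
  expect_equal(max(abs(deltaOD(mv))), 0)
  # I = I0 / e -> dOD = 1
  fr <- frames(mv)
  fr[, , , 60:300] <- 1000 / exp(1)
  mv2 <- MultispectralStack(fr, rate_hz = 10, trigger_s = 0)
  dod <- deltaOD(mv2)
  expect_equal(dod[1, 1, 1, 100], 1, tolerance = 1e-12)
  # non-positive intensities are masked with a warning
  fr[1, 1, 1, 100] <- 0
  expect_warning(d3 <- deltaOD(MultispectralStack(fr, rate_hz = 10,
                                                  trigger_s = 0)),
                 "non-positive")
  expect_true(is.na(d3[1, 1, 1, 100]))
})

test_that("a unit pulse in dHbO produces dOD = eps_HbO * L at each wavelength", {
  nt <- 300
  pulse <- 1e-6
  hbo <- numeric(nt); hbo[100:150] <- pulse
  sp <- hemoForwardSpec(dHbO_t = hbo, dHbR_t = numeric(nt),
                        spatial_kernel = matrix(1, 2, 2), n_trials = 1)
  mv <- genMultispectralMovie(sp)
  dod <- deltaOD(mv)
  ext <- defaultExtinctionTable(); pl <- defaultPathlengthTable()
  for (l in 1:3)   # hand-evaluate the forward product per wavelength
    expect_equal(dod[1, 1, l, 120], ext$eps_hbo[l] * pulse * pl$L_cm[l],
                 tolerance = 1e-10)
})

test_that("the full chain round-trips the generator's concentrations at zero noise", {
  set.seed(8)
  kern <- matrix(runif(48, 0.2, 1), 6, 8)
  sp <- hemoForwardSpec(spatial_kernel = kern, n_trials = 2)
  mv <- genMultispectralMovie(sp)
  dod <- deltaOD(mv)
  mua <- invertMua(dod, defaultPathlengthTable(), wavelengths(mv))
  hs <- solveHemoglobin(mua, defaultExtinctionTable(), wavelengths(mv))
  truth_hbo <- outer(as.vector(kern), rep(sp$dHbO_t, 2))
  truth_hbr <- outer(as.vector(kern), rep(sp$dHbR_t, 2))
  scale <- max(abs(truth_hbo))
  expect_lt(max(abs(as.vector(hbo(hs)) - as.vector(truth_hbo))) / scale,
            1e-10)
  expect_lt(max(abs(as.vector(hbr(hs)) - as.vector(truth_hbr))) / scale,
            1e-10)
  # dHbT is the sum by construction
  expect_identical(hbt(hs), hbo(hs) + hbr(hs))
})

test_that("the forward model is linear: doubling concentrations doubles dOD", {
  nt <- 300
  tc <- blockResponseTimecourse()
  sp1 <- hemoForwardSpec(dHbO_t = tc$dHbO, dHbR_t = tc$dHbR,
                         spatial_kernel = matrix(1, 2, 2), n_trials = 1)
  sp2 <- hemoForwardSpec(dHbO_t = 2 * tc$dHbO, dHbR_t = 2 * tc$dHbR,
                         spatial_kernel = matrix(1, 2, 2), n_trials = 1)
  d1 <- deltaOD(genMultispectralMovie(sp1))
  d2 <- deltaOD(genMultispectralMovie(sp2))
  expect_equal(2 * d1, d2, tolerance = 1e-12)
})

test_that("solver contracts: underdetermined and ill-conditioned systems are rejected", {
  mua1 <- array(0, c(2, 2, 1, 4))
  expect_error(solveHemoglobin(mua1, defaultExtinctionTable(), 530),
               "two wavelengths")
  mua2 <- array(0, c(2, 2, 2, 4))
  degen <- data.frame(wavelength_nm = c(470, 530),
                      eps_hbo = c(1, 1), eps_hbr = c(1 + 1e-12, 1))
  expect_error(solveHemoglobin(mua2, degen, c(470, 530)), "ill-conditioned")
  # zero absorption solves to exactly zero concentrations
  hs <- solveHemoglobin(array(0, c(2, 2, 3, 4)), defaultExtinctionTable(),
                        c(470, 530, 625))
  expect_true(all(hbo(hs) == 0) && all(hbr(hs) == 0))
  # a missing wavelength in the tables is a hard error
  sp <- hemoForwardSpec(wavelengths = c(470, 800),
                        spatial_kernel = matrix(1, 2, 2), n_trials = 1)
  expect_error(genMultispectralMovie(sp), "missing wavelength")
})

test_that("block averaging reduces to a single trial and drops truncated ones", {
  kern <- matrix(runif(16), 4)
  sp <- hemoForwardSpec(spatial_kernel = kern, n_trials = 3)
  mv <- genMultispectralMovie(sp)
  hs <- solveHemoglobin(invertMua(deltaOD(mv), defaultPathlengthTable(),
                                  wavelengths(mv)),
                        defaultExtinctionTable(), wavelengths(mv))
  ba <- blockAverage(hs, trigger_s = triggerTimes(mv))
  expect_equal(ba$n_trials_used, 3)
  # identical trials: the average equals any single trial
  expect_equal(hbt(ba$trial), hbt(hs)[, , 1:300], tolerance = 1e-12)
  # response map is proportional to the spatial kernel (linearity)
  expect_equal(cor(as.vector(ba$response_map), as.vector(kern)), 1,
               tolerance = 1e-10)
  # truncated final trial dropped with a warning
  hs_cut <- new("HemodynamicSeries", dHbO = hbo(hs)[, , 1:700],
                dHbR = hbr(hs)[, , 1:700], rateHz = 10)
  expect_warning(ba2 <- blockAverage(hs_cut, trigger_s = c(0, 30, 60)),
                 "truncated")
  expect_equal(ba2$n_trials_used, 2)
})

test_that("with 1% noise and 20-trial averaging the response map correlates r > 0.95", {
  g <- seq(-1, 1, length.out = 16)
  kern <- outer(g, g, function(x, y) exp(-(x^2 + y^2) / 0.18))
  sp <- hemoForwardSpec(spatial_kernel = kern, n_trials = 20, noise_sd = 0.01)
  mv <- genMultispectralMovie(sp, seed = 99L)
  hs <- solveHemoglobin(invertMua(deltaOD(mv), defaultPathlengthTable(),
                                  wavelengths(mv)),
                        defaultExtinctionTable(), wavelengths(mv))
  ba <- blockAverage(hs, trigger_s = triggerTimes(mv))
  expect_gt(cor(as.vector(ba$response_map), as.vector(kern)), 0.95)
})

test_that("responseROI proposes the half-maximum region of a Gaussian blob", {
  g <- seq(-2, 2, length.out = 41)
  blob <- outer(g, g, function(x, y) exp(-(x^2 + y^2) / 0.5))
  roi <- responseROI(blob, 0.5)
  # analytic half-max radius: r = sqrt(0.5 * log(2)) in g units
  r_ana <- sqrt(0.5 * log(2))
  rr <- sqrt(outer(g^2, g^2, "+"))
  expect_true(all(roi$mask[rr <= r_ana - 0.11]))   # one grid step inside
  expect_true(!any(roi$mask[rr >= r_ana + 0.11]))
  expect_true(roi$localized)
  expect_warning(u <- responseROI(matrix(1, 8, 8), 0.5), "non-localized")
  expect_false(u$localized)
  expect_error(responseROI(matrix(0, 8, 8), 0.5), "empty")
})
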
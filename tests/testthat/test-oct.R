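# Angiogram construction, capillary segmentation, ring densities, statistics.

phantom_spec <- function(...) {
  angioPhantomSpec(volume_shape = c(96L, 96L, 40L),
                   voxel_size_um = c(1.5, 1.5, 3), ...)
}

test_that("phantom ground truth obeys its ablation contract", {
  # ablation_survival = 1: identical truth to the unablated phantom
  a <- genAngiogramPhantom(phantom_spec(ablation_radius_um = 50,
                                        ablation_survival = 1),
                           n_acquisitions = 1, seed = 9L)
  b <- genAngiogramPhantom(phantom_spec(), n_acquisitions = 1, seed = 9L)
  expect_identical(a$truth_mask, b$truth_mask)
  # survival 0 at radius 50: brute-force distance count finds no survivor
  c0 <- genAngiogramPhantom(phantom_spec(ablation_radius_um = 50,
                                         ablation_survival = 0),
                            n_acquisitions = 1, seed = 9L)
  d <- dim(c0$truth_mask)
  cx <- (matrix(seq_len(d[1]), d[1], d[2]) - 0.5) * 1.5
  cy <- (matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - 0.5) * 1.5
  inside <- array(sqrt((cx - 72)^2 + (cy - 72)^2) <= 50, d)
  expect_identical(sum(c0$truth_mask & inside), 0L)
  expect_identical(c0$truth_mask & !inside, b$truth_mask & !inside)
  # oversized ablation radius warns that the rings will leave the field
  expect_warning(genAngiogramPhantom(phantom_spec(ablation_radius_um = 100,
                                                  ablation_survival = 0),
                                     n_acquisitions = 1, seed = 1L),
                 "half the field")
})

test_that("angiogram contrast is zero for static tissue and bright at flow", {
  # noise-free, no flow anywhere: difference volume is exactly zero
  ph0 <- genAngiogramPhantom(phantom_spec(capillary_fraction = 0,
                                          surface_vessel_depth_um = 0),
                             n_acquisitions = 2, noise_sd = 0, seed = 2L)
  v0 <- angioVoxels(buildAngiogram(ph0$repeats))
  expect_true(all(v0 == 0))
  # noise-free with flow: bright exactly at flowing voxels
  ph1 <- genAngiogramPhantom(phantom_spec(), n_acquisitions = 2,
                             noise_sd = 0, seed = 2L)
  v1 <- angioVoxels(buildAngiogram(ph1$repeats))
  expect_true(all(v1[!ph1$flow_mask] == 0))
  expect_gt(mean(v1[ph1$flow_mask] > 0), 0.999)
  # identical repeats everywhere -> zero volume
  rep1 <- ph1$repeats[[1]]; rep1[, , , 2] <- rep1[, , , 1]
  expect_true(all(angioVoxels(buildAngiogram(list(rep1))) == 0))
  expect_error(buildAngiogram(list(rep1[, , , 1, drop = FALSE])), "2 repeats")
})

test_that("averaging more repeats lowers the background variance ~ 1/n", {
  spec <- phantom_spec(capillary_fraction = 0)
  ph20 <- genAngiogramPhantom(spec, n_acquisitions = 20, seed = 6L)
  ph2 <- genAngiogramPhantom(spec, n_acquisitions = 2, seed = 7L)
  # restrict to static voxels: the pial tree's flow contrast would add an
  # n-independent between-population variance term
  st20 <- !ph20$flow_mask
  bg20 <- angioVoxels(buildAngiogram(ph20$repeats))[st20]
  bg2 <- angioVoxels(buildAngiogram(ph2$repeats))[!ph2$flow_mask]
  ratio <- var(bg2) / var(bg20)
  expect_equal(ratio, 10, tolerance = 0.15)
})

test_that("segmentation recovers the phantom truth (Dice > 0.95, density within 10%)", {
  for (frac in c(0.02, 0.05, 0.10)) {
    ph <- genAngiogramPhantom(phantom_spec(capillary_fraction = frac),
                              n_acquisitions = 6, seed = 31L)
    cm <- segmentCapillaries(buildAngiogram(ph$repeats,
                                            c(1.5, 1.5, 3)),
                             slab_top_um = 18, slab_thickness_um = 100)
    s <- segmentation_vs_truth(ph, cm)
    expect_gt(s$dice, 0.95)
    expect_lt(abs(s$est_density / s$truth_density - 1), 0.10)
  }
  # degenerate inputs
  zero_vol <- new("AngiogramVolume", voxels = array(0, c(24, 24, 24)),
                  voxelSizeUm = c(1.5, 1.5, 3), nRepeatsAveraged = 1L)
  cm0 <- segmentCapillaries(zero_vol, slab_top_um = 6,
                            slab_thickness_um = 30)
  expect_identical(capillaryDensity(cm0), 0)
  expect_error(segmentCapillaries(zero_vol, slab_top_um = 500,
                                  slab_thickness_um = 30), "outside")
})

test_that("ring partition is complete and disjoint (brute-force check)", {
  mask <- new("CapillaryMask",
              mask = array(TRUE, c(40, 40, 4)), slabUm = c(0, 12),
              exclusion = matrix(FALSE, 40, 40),
              voxelSizeUm = c(5, 5, 3), density = 1)
  prof <- ringDensity(mask, c(100, 100), r_start_um = 20, r_end_um = 80,
                      ring_width_um = 20)
  cx <- (matrix(seq_len(40), 40, 40) - 0.5) * 5
  cy <- t(cx)
  rr <- sqrt((cx - 100)^2 + (cy - 100)^2)
  n_brute <- sum(rr >= 20 & rr < 80) * 4L
  expect_identical(sum(prof$n_voxels), n_brute)
  # each annulus counted once: per-ring brute force agrees
  for (i in seq_len(nrow(prof)))
    expect_identical(prof$n_voxels[i],
                     sum(rr >= prof$r_inner_um[i] &
                           rr < prof$r_outer_um[i]) * 4L)
})

test_that("normalized baseline profile is exactly 1 and ablation depresses only inner rings", {
  base <- genAngiogramPhantom(phantom_spec(capillary_fraction = 0.08),
                              n_acquisitions = 6, seed = 13L)
  cm_b <- segmentCapillaries(buildAngiogram(base$repeats, c(1.5, 1.5, 3)),
                             18, 100)
  prof_b <- ringDensity(cm_b, c(72, 72), 20, 70, 25, baseline = NULL)
  self_norm <- ringDensity(cm_b, c(72, 72), 20, 70, 25, baseline = prof_b)
  expect_equal(self_norm$normalized, rep(1, nrow(self_norm)))
  # ablation to radius 45: inner ring depressed, outer ring ~ baseline
  abl <- genAngiogramPhantom(phantom_spec(capillary_fraction = 0.08,
                                          ablation_radius_um = 45,
                                          ablation_survival = 0),
                             n_acquisitions = 6, seed = 14L)
  cm_a <- segmentCapillaries(buildAngiogram(abl$repeats, c(1.5, 1.5, 3)),
                             18, 100)
  prof_a <- ringDensity(cm_a, c(72, 72), 20, 70, 25, baseline = prof_b)
  expect_lt(prof_a$normalized[1], 0.35)
  expect_gt(prof_a$normalized[2], 0.75)
  # empty mask: zero densities
  empty <- new("CapillaryMask", mask = array(FALSE, c(40, 40, 4)),
               slabUm = c(0, 12), exclusion = matrix(FALSE, 40, 40),
               voxelSizeUm = c(5, 5, 3), density = 0)
  expect_true(all(ringDensity(empty, c(100, 100), 20, 80, 20)$density == 0))
  expect_error(ringDensity(empty, c(1000, 0), 20, 80, 20), "within the field")
})

test_that("group statistics match hand calculations and flag effects", {
  # identical groups: t = 0, p = 1
  d_same <- data.frame(value = rep(c(0.3, 0.4, 0.5), 2),
                       group = rep(c("a", "b"), each = 3), phase = "pre")
  r <- compareGroups(d_same)
  expect_equal(r$t_tests$t, 0)
  expect_equal(r$t_tests$p, 1)
  # printed toy densities vs the textbook pooled-variance formula
  a <- c(0.38, 0.41, 0.42); b <- c(0.19, 0.21, 0.20)
  d2 <- data.frame(value = c(a, b), group = "opt",
                   phase = rep(c("pre", "post"), each = 3))
  r2 <- compareGroups(d2)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r2$t_tests$t, t_hand, tolerance = 1e-12)
  expect_true(r2$t_tests$significant)
  # a d = 3 effect at n = 3 with a fixed draw is flagged significant
  set.seed(1)
  eff <- data.frame(value = c(rnorm(3, 0, 0.02), rnorm(3, 0.06, 0.02)),
                    group = "opt", phase = rep(c("pre", "post"), each = 3))
  expect_true(any(compareGroups(eff)$t_tests$significant))
  # ANOVA over 2x2 cells reports a finite F and post hoc matrix
  d4 <- data.frame(value = c(a, b, a + 0.1, b + 0.1),
                   group = rep(c("opt", "non"), each = 6),
                   phase = rep(rep(c("pre", "post"), each = 3), 2))
  r4 <- compareGroups(d4)
  expect_true(is.finite(r4$anova$F))
  expect_identical(dim(r4$posthoc), c(3L, 3L))
  expect_error(compareGroups(data.frame(value = 1, group = "a",
                                        phase = "pre")), ">= 2")
})
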
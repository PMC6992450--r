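## Synthetic OCT angiogram phantoms with known flowing-capillary truth.

#' Specification of an angiogram phantom
#'
#' Geometry and ground truth of a synthetic OCT volume: a deterministic pial
#' tree in a surface stratum (one target branch crossing the field plus two
#' collateral branches), a flowing-capillary bed of Poisson-dispersed short
#' capillary segments beneath it, and a controllable ablation region in
#' which only a fraction of capillaries survive.
#'
#' @param volume_shape c(nx, ny, nz) voxels.
#' @param voxel_size_um c(x, y, z) voxel size (um); 1.5-um lateral default.
#' @param capillary_fraction baseline fraction of flowing-capillary voxels in
#'   [0, 1].
#' @param ablation_center_um c(x, y) of the illumination site (um); defaults
#'   to the field center.
#' @param ablation_radius_um lateral radius of the ablated disc (um), >= 0.
#' @param ablation_survival fraction of capillaries retained inside the
#'   radius, in [0, 1]; 1 means no ablation.
#' @param surface_vessel_depth_um depth of the pial-vessel stratum (um); the
#'   capillary bed and analysis slab lie below it.
#' @return A list of class "AngioPhantomSpec".
#' @export
angioPhantomSpec <- function(volume_shape = c(128L, 128L, 64L),
                             voxel_size_um = c(1.5, 1.5, 3),
                             capillary_fraction = 0.05,
                             ablation_center_um = NULL,
                             ablation_radius_um = 0,
                             ablation_survival = 1,
                             surface_vessel_depth_um = 15) {
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 8L),
            length(voxel_size_um) == 3L, all(voxel_size_um > 0),
            capillary_fraction >= 0, capillary_fraction <= 1,
            ablation_radius_um >= 0,
            ablation_survival >= 0, ablation_survival <= 1,
            surface_vessel_depth_um >= 0)
  if (is.null(ablation_center_um))
    ablation_center_um <- volume_shape[1:2] * voxel_size_um[1:2] / 2
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_size_um = voxel_size_um,
                 capillary_fraction = capillary_fraction,
                 ablation_center_um = ablation_center_um,
                 ablation_radius_um = ablation_radius_um,
                 ablation_survival = ablation_survival,
                 surface_vessel_depth_um = surface_vessel_depth_um),
            class = "AngioPhantomSpec")
}

# Lateral footprint of the deterministic pial tree: one target branch
# through the field center plus two diagonal collaterals.
.pialFootprint <- function(nx, ny, voxel_lat) {
  hw <- max(1L, round(15 / voxel_lat))   # ~30-um-wide vessels
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  target <- abs(ys - ny / 2) <= hw
  col1 <- abs((xs - ys) - round(nx / 4)) <= hw
  col2 <- abs((xs + ys) - round(3 * nx / 2)) <= hw
  target | col1 | col2
}

#' Generate an OCT angiogram phantom with known truth
#'
#' Produces repeated B-scan volumes in which flowing voxels (pial tree plus
#' capillary bed, after ablation) take independent values between the two
#' repeats of each acquisition, while static voxels differ only by the
#' declared additive noise. The ground-truth flowing-capillary mask (the
#' capillary bed only, below the pial stratum) is returned alongside.
#'
#' @param spec An "AngioPhantomSpec".
#' @param n_acquisitions number of repeat-pair acquisitions (the analysis
#'   protocol averages 20).
#' @param static_level mean OCT intensity of static tissue.
#' @param flow_mean,flow_sd intensity distribution of flowing voxels (drawn
#'   independently per repeat).
#' @param noise_sd additive Gaussian noise on every voxel of every repeat.
#' @param seed integer seed; the generator is a pure function of
#'   (spec, arguments, seed).
#' @return List with \code{repeats} (list of 4-D arrays nx x ny x nz x 2),
#'   \code{truth_mask} (logical 3-D capillary truth), \code{flow_mask}
#'   (all flowing voxels incl. pial vessels), \code{surface_footprint}
#'   (lateral pial footprint) and the spec echo.
#' @export
genAngiogramPhantom <- function(spec, n_acquisitions = 20L,
                                static_level = 100, flow_mean = 150,
                                flow_sd = 40, noise_sd = 5, seed = 1L) {
  stopifnot(inherits(spec, "AngioPhantomSpec"), n_acquisitions >= 1L)
  d <- spec$volume_shape
  vx <- spec$voxel_size_um
  field <- d[1:2] * vx[1:2]
  if (spec$ablation_radius_um > min(field) / 2)
    warning("ablation radius exceeds half the field: rings will leave it")

  .withSeed(seed, {
    surface_k <- min(d[3], max(0L, ceiling(spec$surface_vessel_depth_um / vx[3])))
    pial2d <- .pialFootprint(d[1], d[2], vx[1])
    flow <- array(FALSE, d)
    if (surface_k > 0L)
      flow[, , seq_len(surface_k)] <- pial2d   # recycled per layer

    truth <- array(FALSE, d)
    if (surface_k < d[3]) {
      # Poisson-dispersed short capillary segments (single-voxel calibre,
      # ~9 um long) filling the requested flowing fraction of the bed
      sub0 <- surface_k + 1L
      nz_sub <- d[3] - surface_k
      seg_um <- 9
      len_vox <- pmax(5L, round(seg_um / vx))       # per-axis length, >= 5 vox
      vol_sub <- d[1] * d[2] * nz_sub
      mean_len <- mean(len_vox)
      n_seg <- round(spec$capillary_fraction * vol_sub / mean_len)
      if (n_seg > 0) {
        axes <- sample.int(3L, n_seg, replace = TRUE)
        lims <- c(d[1], d[2], nz_sub)
        for (s in seq_len(n_seg)) {
          ax <- axes[s]
          L <- min(len_vox[ax], lims[ax])
          p0 <- c(sample.int(d[1] - (ax == 1L) * (L - 1L), 1L),
                  sample.int(d[2] - (ax == 2L) * (L - 1L), 1L),
                  sample.int(nz_sub - (ax == 3L) * (L - 1L), 1L))
          run <- seq.int(p0[ax], length.out = L)
          if (ax == 1L) truth[run, p0[2], sub0 - 1L + p0[3]] <- TRUE
          else if (ax == 2L) truth[p0[1], run, sub0 - 1L + p0[3]] <- TRUE
          else truth[p0[1], p0[2], sub0 - 1L + run] <- TRUE
        }
      }
    }
    # ablation: keep capillaries inside the disc with prob ablation_survival
    if (spec$ablation_radius_um > 0 && spec$ablation_survival < 1) {
      cx <- (matrix(seq_len(d[1]), d[1], d[2]) - 0.5) * vx[1]
      cy <- (matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - 0.5) * vx[2]
      r2 <- (cx - spec$ablation_center_um[1])^2 +
            (cy - spec$ablation_center_um[2])^2
      inside2d <- r2 <= spec$ablation_radius_um^2
      inside <- array(inside2d, d)              # recycled along z
      hit <- which(truth & inside)
      if (length(hit)) {
        drop <- stats::runif(length(hit)) >= spec$ablation_survival
        truth[hit[drop]] <- FALSE
      }
    }
    flow <- flow | truth
    nf <- sum(flow)

    reps <- vector("list", n_acquisitions)
    for (a in seq_len(n_acquisitions)) {
      pair <- array(static_level, c(d, 2L))
      for (r in 1:2) {
        v <- array(static_level, d)
        if (nf)
          v[flow] <- stats::rnorm(nf, flow_mean, flow_sd)
        if (noise_sd > 0)
          v <- v + stats::rnorm(length(v), sd = noise_sd)
        pair[, , , r] <- v
      }
      reps[[a]] <- pair
    }
    list(repeats = reps, truth_mask = truth, flow_mask = flow,
         surface_footprint = pial2d, spec = spec)
  })
}
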
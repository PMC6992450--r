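## OCT angiography: angiogram construction, capillary segmentation,
## ring-density profiles and group statistics.

#' Build an angiogram from repeated B-scans
#'
#' Motion contrast by frame-to-frame subtraction: for each acquisition the
#' magnitude of the difference between the two repeated B-scan volumes is
#' taken, and the per-voxel mean over all acquisitions is returned. Static
#' tissue yields (near) zero difference; moving red blood cells decorrelate
#' the signal between repeats and appear bright.
#'
#' @param bscan_repeats list of 4-D arrays (nx x ny x nz x n_rep, n_rep >= 2)
#'   as produced by \code{\link{genAngiogramPhantom}}; consecutive repeats
#'   are differenced.
#' @param voxel_size_um voxel size (x, y, z) in um.
#' @return An \linkS4class{AngiogramVolume}.
#' @export
buildAngiogram <- function(bscan_repeats, voxel_size_um = c(1.5, 1.5, 3)) {
  stopifnot(is.list(bscan_repeats), length(bscan_repeats) >= 1L)
  d0 <- dim(bscan_repeats[[1]])
  if (length(d0) != 4L || d0[4] < 2L)
    stop("each acquisition needs >= 2 repeats (4-D array)")
  acc <- array(0, d0[1:3])
  npairs <- 0L
  for (a in bscan_repeats) {
    if (!identical(dim(a), d0))
      stop("mismatched repeat shapes across acquisitions")
    for (r in seq_len(d0[4] - 1L)) {
      acc <- acc + abs(a[, , , r + 1L] - a[, , , r])
      npairs <- npairs + 1L
    }
  }
  new("AngiogramVolume", voxels = acc / npairs,
      voxelSizeUm = voxel_size_um,
      nRepeatsAveraged = npairs)
}

#' Segment flowing capillaries in a sub-surface slab
#'
#' Thresholds the flow-contrast volume inside a 150-um-thick slab below the
#' surface vessels. The noise floor is estimated robustly (median + k * MAD
#' of the included slab voxels, which are overwhelmingly static background at
#' physiological capillary fractions), components smaller than
#' \code{min_voxels} are removed, and the lateral footprint of the large
#' surface vessels (depth-projected, thresholded and dilated) is excluded.
#'
#' @param vol An \linkS4class{AngiogramVolume}.
#' @param slab_top_um top of the analysis slab (um below the surface).
#' @param slab_thickness_um slab thickness (um), 150 by default.
#' @param exclusion "auto" to derive the surface-vessel footprint from the
#'   volume itself, a logical lateral matrix, or NULL for no exclusion.
#' @param k_sd threshold in robust standard deviations above the floor.
#' @param min_voxels connected components smaller than this are discarded.
#' @param dilate_px dilation of the surface-vessel footprint (voxels).
#' @return A \linkS4class{CapillaryMask}; its \code{capillaryDensity()} is
#'   the flowing fraction of included slab voxels.
#' @export
segmentCapillaries <- function(vol, slab_top_um = 18,
                               slab_thickness_um = 150,
                               exclusion = "auto", k_sd = 3,
                               min_voxels = 5L, dilate_px = 2L) {
  stopifnot(is(vol, "AngiogramVolume"), slab_thickness_um > 0)
  v <- angioVoxels(vol)
  d <- dim(v)
  vz <- voxelSize(vol)[3]
  zc <- (seq_len(d[3]) - 0.5) * vz
  slab_lo <- slab_top_um
  slab_hi <- slab_top_um + slab_thickness_um
  in_slab_z <- zc >= slab_lo & zc < slab_hi
  if (!any(in_slab_z)) stop("slab lies outside the volume depth")

  if (identical(exclusion, "auto")) {
    surf_z <- zc < slab_lo
    if (any(surf_z)) {
      proj <- apply(v[, , surf_z, drop = FALSE], c(1, 2), max)
      thr_s <- stats::median(proj) + k_sd * stats::mad(proj)
      excl <- .dilateSquare(proj > thr_s & thr_s > 0, as.integer(dilate_px))
    } else {
      excl <- matrix(FALSE, d[1], d[2])
    }
  } else if (is.null(exclusion)) {
    excl <- matrix(FALSE, d[1], d[2])
  } else {
    stopifnot(is.logical(exclusion), identical(dim(exclusion), d[1:2]))
    excl <- exclusion
  }

  included <- array(FALSE, d)
  included[, , in_slab_z] <- !excl   # lateral matrix recycled per layer
  if (!any(included)) stop("empty slab after surface-vessel exclusion")

  vals <- v[included]
  floor_ <- stats::median(vals)
  thr <- floor_ + k_sd * stats::mad(vals)
  # threshold and de-speckle on the full volume, then clip to the slab, so
  # that objects straddling a slab face keep their full support
  mask <- v > thr
  if (min_voxels > 1L && any(mask)) {
    lab <- .labelArray(mask)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_voxels)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  mask <- mask & included

  new("CapillaryMask", mask = mask, slabUm = c(slab_lo, slab_hi),
      exclusion = excl, voxelSizeUm = voxelSize(vol),
      density = mean(mask[included]))
}

#' Radial ring-density profile of a capillary mask
#'
#' Flowing-capillary fraction in concentric half-open lateral annuli
#' [r, r + width) around the illumination center: 50-um rings from 100 um
#' out to 300 um by default. Rings are disjoint and cover the annulus
#' completely; a ring lying entirely outside the field is flagged missing.
#' When a baseline profile is supplied the densities are normalized ring-wise
#' to it.
#'
#' @param mask A \linkS4class{CapillaryMask}.
#' @param center_um c(x, y) of the illumination center (um, field
#'   coordinates).
#' @param r_start_um,r_end_um,ring_width_um ring geometry (um); defaults
#'   100, 300, 50.
#' @param baseline optional baseline profile (data.frame from this function)
#'   for ring-wise normalization.
#' @return data.frame with r_inner_um, r_outer_um, n_voxels, n_flowing,
#'   density, missing, and (with a baseline) normalized.
#' @export
ringDensity <- function(mask, center_um, r_start_um = 100, r_end_um = 300,
                        ring_width_um = 50, baseline = NULL) {
  stopifnot(is(mask, "CapillaryMask"), length(center_um) == 2L,
            ring_width_um > 0, r_end_um > r_start_um)
  m <- maskArray(mask)
  d <- dim(m)
  vx <- voxelSize(mask)
  field <- d[1:2] * vx[1:2]
  if (any(center_um < 0) || any(center_um > field))
    stop("center must lie within the field")
  zc <- (seq_len(d[3]) - 0.5) * vx[3]
  in_slab_z <- zc >= slabRange(mask)[1] & zc < slabRange(mask)[2]
  excl <- exclusionMask(mask)

  cx <- (matrix(seq_len(d[1]), d[1], d[2]) - 0.5) * vx[1]
  cy <- (matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - 0.5) * vx[2]
  rr <- sqrt((cx - center_um[1])^2 + (cy - center_um[2])^2)

  inner <- seq(r_start_um, r_end_um - ring_width_um, by = ring_width_um)
  nz <- sum(in_slab_z)
  out <- lapply(inner, function(r0) {
    ring2d <- rr >= r0 & rr < r0 + ring_width_um & !excl
    n_inc <- sum(ring2d) * nz
    if (n_inc == 0L)
      return(data.frame(r_inner_um = r0, r_outer_um = r0 + ring_width_um,
                        n_voxels = 0L, n_flowing = 0L, density = NA_real_,
                        missing = TRUE))
    nf <- sum(m[array(ring2d, d) & rep(in_slab_z, each = d[1] * d[2])])
    data.frame(r_inner_um = r0, r_outer_um = r0 + ring_width_um,
               n_voxels = n_inc, n_flowing = nf, density = nf / n_inc,
               missing = FALSE)
  })
  prof <- do.call(rbind, out)
  if (!is.null(baseline)) {
    stopifnot(identical(baseline$r_inner_um, prof$r_inner_um))
    prof$normalized <- prof$density / baseline$density
  }
  prof
}

#' Group statistics for capillary densities
#'
#' The statistical battery applied to density observations: cell means and
#' standard deviations, pooled-variance two-sample t-tests of before vs
#' after within each protocol and of protocol vs protocol within each phase,
#' and a one-way ANOVA over all cells with post hoc pairwise t-tests.
#' Significance is flagged at \code{alpha} (0.05 by default).
#'
#' @param data data.frame with a numeric \code{value} column and factors
#'   \code{group} (e.g. protocol) and \code{phase} (e.g. before/after).
#' @param alpha significance level.
#' @return List with \code{cells} (per-cell n/mean/sd), \code{t_tests}
#'   (one row per comparison with t, df, p, significant), \code{anova}
#'   (F, df, p) and \code{posthoc} (pairwise t-test p matrix).
#' @export
compareGroups <- function(data, alpha = 0.05) {
  stopifnot(is.data.frame(data),
            all(c("value", "group", "phase") %in% names(data)))
  data$group <- as.character(data$group)
  data$phase <- as.character(data$phase)
  cell <- interaction(data$group, data$phase, drop = TRUE)
  if (any(table(cell) < 2L))
    stop("each group x phase cell needs >= 2 observations")

  cells <- do.call(rbind, lapply(split(data, cell), function(d)
    data.frame(group = d$group[1], phase = d$phase[1], n = nrow(d),
               mean = mean(d$value), sd = stats::sd(d$value))))
  rownames(cells) <- NULL

  tt_row <- function(a, b, label) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(comparison = label, mean_1 = mean(a), mean_2 = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, significant = tt$p.value < alpha)
  }
  tests <- list()
  phases <- unique(data$phase)
  groups <- unique(data$group)
  if (length(phases) >= 2L)
    for (g in groups) {
      for (i in seq_len(length(phases) - 1L))
        for (j in (i + 1L):length(phases)) {
          a <- data$value[data$group == g & data$phase == phases[i]]
          b <- data$value[data$group == g & data$phase == phases[j]]
          tests[[length(tests) + 1L]] <-
            tt_row(a, b, paste0(g, ": ", phases[i], " vs ", phases[j]))
        }
    }
  if (length(groups) >= 2L)
    for (ph in phases)
      for (i in seq_len(length(groups) - 1L))
        for (j in (i + 1L):length(groups)) {
          a <- data$value[data$group == groups[i] & data$phase == ph]
          b <- data$value[data$group == groups[j] & data$phase == ph]
          tests[[length(tests) + 1L]] <-
            tt_row(a, b, paste0(ph, ": ", groups[i], " vs ", groups[j]))
        }
  t_tests <- if (length(tests)) do.call(rbind, tests) else NULL

  anova_tab <- NULL
  posthoc <- NULL
  if (nlevels(cell) >= 2L) {
    fit <- stats::aov(value ~ cell, data = data.frame(value = data$value,
                                                      cell = cell))
    s <- summary(fit)[[1]]
    anova_tab <- data.frame(F = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
                            p = s$`Pr(>F)`[1],
                            significant = s$`Pr(>F)`[1] < alpha)
    posthoc <- stats::pairwise.t.test(data$value, cell,
                                      p.adjust.method = "none")$p.value
  }
  list(cells = cells, t_tests = t_tests, anova = anova_tab,
       posthoc = posthoc, alpha = alpha)
}
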
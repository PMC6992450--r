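# Shared fixture builders. Everything is generated in code at test time.

# A small homogeneous phantom with uniform tau_c.
uniform_phantom <- function(n = 64L, tau = 20e-6, beta = 1) {
  FlowPhantom(matrix(tau, n, n), beta = beta)
}

# Fluence grid with a laterally peaked exp(-z / zeta_um) profile, built by
# hand to test activationDepth against its closed form.
exp_decay_grid <- function(zeta_um, voxel_um = 10, nz = 60L, nxy = 5L) {
  dep <- array(0, c(nxy, nxy, nz))
  z <- (seq_len(nz) - 1L) * voxel_um   # depth of each layer's focal offset
  mid <- (nxy + 1L) %/% 2L
  for (k in seq_len(nz)) dep[mid, mid, k] <- exp(-z[k] / zeta_um)
  new("FluenceGrid", deposited = dep, voxelSizeUm = voxel_um,
      nPhotons = 1, escapedWeight = 0, seed = 0,
      beam = list(), tissue = list())
}

# Truth-aware summary of a segmentation against its phantom.
segmentation_vs_truth <- function(ph, cm) {
  truth <- ph$truth_mask
  d <- dim(truth)
  vz <- voxelSize(cm)[3]
  zc <- (seq_len(d[3]) - 0.5) * vz
  slab <- slabRange(cm)
  insl <- array(rep(zc >= slab[1] & zc < slab[2], each = d[1] * d[2]), d) &
    !array(exclusionMask(cm), d)
  m <- maskArray(cm)
  list(dice = 2 * sum(m & truth & insl) /
         (sum(m & insl) + sum(truth & insl)),
       est_density = capillaryDensity(cm),
       truth_density = mean(truth[insl]))
}
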
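---
title: "Models and methods behind PhotoStroke"
author: "PhotoStroke authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind PhotoStroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhotoStroke)
```

PhotoStroke implements the analysis chain of an awake-mouse targeted
photothrombosis experiment — speckle flowmetry with closed-loop illumination
guidance, multispectral hemodynamics, photon-transport dosimetry, OCT
capillary densitometry and cylinder-test scoring — together with synthetic
generators that produce every input with known ground truth. This vignette
explains the models, the parameters that matter, the numerical choices, and
what the synthetic tests do and do not establish about real data.

## Speckle flowmetry

### The contrast model

A camera integrating a dynamic speckle field over an exposure $T$ sees a
washed-out pattern whose spatial contrast $K = \sigma_s/\bar I$ depends on
the ratio $x = T/\tau_c$, where $\tau_c$ is the speckle decorrelation time
(inversely related to scatterer speed). For an exponentially decorrelating
field with coherence factor $\beta$,

$$K(x) = \sqrt{\beta\,\frac{e^{-2x} - 1 + 2x}{2x^2}},$$

implemented in `speckleContrastTheory()` with a series branch below
$x = 10^{-4}$ to avoid cancellation. In the regime of interest
($T = 5$ ms, $\tau_c$ tens of microseconds, so $x \gg 1$) $K^2 \to \beta/x$,
which is why the blood flow index $\mathrm{BFI} = 1/K^2$ is proportional to
$1/\tau_c$ and serves as a relative flow surrogate. The percent BFI drop
between two flow states is therefore available in closed form
(`bfiDropTheory()`) and acts as the oracle for every simulated occlusion:
a five-fold $\tau_c$ increase at 5-ms exposure gives a
`r round(bfiDropTheory(20e-6, 100e-6), 1)`% drop, a 2.5-fold increase a
`r round(bfiDropTheory(20e-6, 50e-6), 1)`% drop — the levels used to confirm
a vessel occlusion and to characterize the stroke core.

### The generator

`genSpeckleStack()` does not simulate electric fields. Each pixel's
intensity is drawn from a gamma distribution with mean equal to the camera
level and relative standard deviation $K(x, \beta)$, independently across
pixels and frames (a speckle grain of one pixel). The empirical spatial
contrast of a homogeneous patch is then an unbiased estimate of
$K$ — which is the only observable the downstream pipeline uses — at a cost
orders of magnitude below a phasor simulation. For $\tau_c \to \infty$ and
$\beta = 1$ the marginal is exponential, i.e. fully developed static
speckle with $K = 1$, as it must be. What this generator does *not*
emulate: spatial speckle grains larger than a pixel, temporal frame-to-frame
correlation, shot noise, and detector nonlinearity. Tests passing on these
stacks show the *analysis* is correct, not that a particular camera meets
the model.

$\beta$ defaults to 1.0 and is configurable; real systems have $\beta < 1$
from depolarization and unresolved speckle. The camera noise of the real
instrument is unknown to us and deliberately not emulated.

### Analysis choices

* **Window**: the conventional 7×7 bin; `spatialContrast()` uses an
  integral-image sliding window with the sample-variance ($n-1$)
  convention.
* **Borders**: symmetric reflection padding by default, so $K$ is defined
  at every pixel; a `"mask"` option leaves a 3-px NA margin instead.
* **Contrast floor**: `bloodFlowIndex()` masks pixels with
  $K < k_\mathrm{floor}$ ($10^{-3}$ by default) rather than letting
  $1/K^2$ blow up.
* **ROI means across flow discontinuities**: a window straddling the edge
  of a vessel mixes two flow regimes and measures neither, so
  `simulateOcclusionDrop()` restricts ROI averages to pixels whose whole
  window lies inside the region. With this restriction the estimator-bias
  of $1/\hat K^2$ (a few percent, from the 49-sample variance estimate)
  cancels almost exactly between the baseline and occluded stacks.
* **Temporal smoothing**: ROI traces use a centered 1-s sliding mean,
  chosen as the shortest kernel that suppresses frame noise at 40 fps
  without hiding the protocol's 5-s persistence window. Gap intervals
  (animal repositioning) are explicit NAs, never interpolated.

### The guidance automaton

The optimized protocol is a deterministic state machine over
percent-of-baseline BFI traces (`occlusionGuidance()`): FULL (0.6 mW) until
the target-vessel drop has held ≥ 80 percentage points, then HALF (0.3 mW)
for exactly 120 s, then OFF; from OFF, a sustained recovery re-arms to FULL.
An occlusion is *confirmed* only when the vessel criterion and a > 50-point
drop in the supplied region hold simultaneously. Two parameters replace an
operator's real-time judgment and are genuinely our choices:

* **Persistence (debounce)**: every criterion must hold continuously for
  5 s (elapsed time, not sample count) before a state change. The real
  decision latency of a human watching a live contrast image is unknowable;
  5 s is long enough to reject single-frame noise at any plausible frame
  rate and short next to the 2-min hold.
* **Re-arm threshold**: the laser re-arms when the vessel drop falls back
  below 50 points (flow above half of baseline). A visible "return of
  blood flow" plainly exceeds half-baseline flow, and separating the 80-point
  occlusion threshold from the 50-point re-arm threshold provides the
  hysteresis that prevents chatter. Both thresholds are parameters of
  `guidanceParams()`.

The fixed-duration control (`nonoptimizedProtocol()`) is a single 15-min
FULL interval. On any trace that reaches occlusion before 15 min, the
optimized controller's total FULL time is necessarily no larger — the
rationale for reduced photodamage — and the test suite checks this
invariant on scripted traces.

## Multispectral hemodynamics

The attenuation model is
$I(\lambda, t) = I_0(\lambda)\,e^{-\Delta\mu_a(\lambda,t) L(\lambda)}$ with
$\Delta\mu_a(\lambda,t) = \varepsilon_\mathrm{HbO}(\lambda)\Delta\mathrm{HbO}(t)
+ \varepsilon_\mathrm{HbR}(\lambda)\Delta\mathrm{HbR}(t)$. The chain
`deltaOD()` → `invertMua()` → `solveHemoglobin()` takes the literal model at
its word: $L(\lambda)$ is the wavelength-dependent mean pathlength entering
the exponent, not a partial-pathlength derivative. $I_0$ is the per-trial
mean of the first 5 s of each trial, so slow drifts between trials do not
leak into responses. The three-wavelength, two-chromophore system is solved
per pixel and time point by ordinary least squares through a precomputed
2×3 pseudoinverse; the extinction matrix's condition number is checked and
a single wavelength is rejected as underdetermined.

The bundled extinction and pathlength tables are representative
literature-magnitude values for 470/530/625 nm; they are configuration
inputs, and every test is a forward/inverse round trip through the *same*
tables, so no result depends on their specific values. `blockAverage()`
aligns on the 5 s baseline / 5 s stimulus / 20 s recovery design (20 trials
by default), drops truncated trials with a warning, and maps the
stimulus-window mean ΔHbT; `responseROI()` proposes the connected
half-maximum region. Choosing the artery that supplies it remains an
operator decision and is out of scope.

The generator inverts this chain exactly at zero noise (round-trip relative
error below $10^{-10}$ in the tests) and adds multiplicative Gaussian
intensity noise when requested; with 1% noise and 20-trial averaging the
recovered response map correlates with the truth kernel at $r > 0.95$.

## Photon-transport dosimetry

Closed forms first: axial PSF $2\lambda/\mathrm{NA}^2$, Rayleigh range
$\pi w_0^2/\lambda$. Two waist conventions circulate for focal spots:
the diffraction-limited $w_0 = 0.61\lambda/\mathrm{NA}$ (which gives
60.8 µm at NA 0.1 and 520 nm) and half the quoted spot diameter (which
gives ≈ 1.4 mm for a 30-µm spot). `rayleighRange()` exposes both through
its `na`/`waist_um` arguments and prefers neither silently.

`runPhotonTransport()` is a standard weighted-photon Monte Carlo walk
(exponential free paths with $\mu_t$, deposition fraction $\mu_a/\mu_t$,
Henyey–Greenstein deflection, Russian roulette below $10^{-4}$ weight with
survival 0.1, normal-incidence Fresnel loss at the surface), written in
C++ with its own seeded RNG so runs are bit-identical per seed. The focus
is placed at the tissue surface, where the pial target vessel lies; photons
launch on a Gaussian spot of the beam waist with directions inside the NA
cone. Tissue defaults ($\mu_a = 0.37$, $\mu_s = 23$ mm⁻¹, $g = 0.89$,
$n = 1.37$) are typical murine-cortex values near 520 nm and are
configurable; no quantitative claim in the package depends on them.

The photosensitizer's activation threshold is not a measured constant, so
`activationDepth()` reports depth as a function of a threshold *fraction*
of focal-plane fluence (default 0.1). Consequently the package asserts the
*ordering* — a tightly focused NA-0.1 beam activates strictly shallower
than a loosely focused NA-0.02 beam at equal power — rather than any exact
depth; with the default threshold and tissue the NA-0.1 beam reaches about
150 µm in our runs. Validation anchors are the scattering-free limit
(deposition $\propto e^{-\mu_a z}$ within 5% over three attenuation
lengths at $10^6$ photons) and per-photon weight conservation to $10^{-3}$.

## OCT capillary densitometry

`buildAngiogram()` takes repeat-to-repeat magnitude differences and
averages the 20 repeat pairs (configurable), the standard decorrelation
contrast: static tissue cancels, moving red blood cells do not.
`segmentCapillaries()` then

1. estimates the noise floor robustly (median + 3 MAD of slab voxels,
   overwhelmingly static background at physiological capillary fractions),
2. thresholds and removes connected components under 5 voxels **on the full
   volume** before clipping to the slab — segmenting inside the slab alone
   would truncate capillaries crossing its faces below the size filter and
   bias density low, which is visible in the phantom tests,
3. excludes the lateral footprint of the large surface vessels
   (depth-projected, thresholded, dilated by 2 voxels), and
4. reports density as the flowing fraction of included voxels in a 150-µm
   slab whose top sits just beneath the surface-vessel stratum
   (configurable `slab_top_um`; the exact stratum depth in the real
   instrument is not knowable from the published analysis).

Density is a dimensionless voxel fraction. A skeletonized length-per-area
density is a plausible alternative definition; it is not implemented, since
a defensible 3-D skeletonization is a project of its own and every
comparison in the package is internally consistent on the voxel fraction.

`ringDensity()` uses half-open lateral annuli $[r, r+50)$ µm — en-face
geometry, no 3-D radius — from 100 to 300 µm by default; the test suite
verifies by brute-force distance counting that the rings partition the
annulus exactly. Normalization is ring-wise against a baseline profile, so
a baseline profile against itself is exactly 1. The phantom places
Poisson-dispersed ~9-µm capillary segments (single-voxel calibre, at least
5 voxels long so they survive the size filter) beneath a deterministic pial
tree of one target branch and two collaterals, and ablation removes a
controllable fraction of capillary voxels inside a disc; recovery of the
ablation radius by the rings is checked against brute-force truth counts.

`compareGroups()` wires the density observations into pooled-variance
two-sample t-tests (before vs after per protocol, protocol vs protocol per
phase), a one-way ANOVA across cells with post hoc pairwise t-tests, and a
0.05 significance flag, via `stats::t.test`/`aov`/`pairwise.t.test`.

## Behavior

`scoreSession()` counts first wall contacts per rear, forms the
contralateral-use fraction $n_c/(n_c + n_i)$ and reports percent change
from each subject's own baseline fraction. The fraction (not the raw
count) is used so session length cancels, and baseline-normalization
absorbs innate paw preference; a post-stroke deficit is a negative
deflection. Zero-rear sessions and zero baseline contra use yield flagged
NAs, never errors. `longitudinalTests()` runs per-timepoint paired t-tests
against baseline with no multiplicity correction by default (the
per-timepoint tests are reported as such; Bonferroni is an option).

## Problem sizes and determinism

Every generator is a pure function of (spec, seed); the Monte Carlo engine
carries its own RNG stream. The default test and demonstration sizes were
chosen as the smallest at which the statistical assertions are comfortably
stable: 128²–256² px speckle frames (giving ≥ 10⁴ pixels per ROI after the
window-interior restriction, the scale at which the 2%-point tolerance on
the confirmation drops is met), 10–100 frames per condition, 96³-scale
angiogram phantoms with 6 repeat pairs, 10⁵–10⁶ photons per transport run,
and 2–20 trials for the hemodynamic movies. The full pipeline demo
(`runPipeline(defaultConfig())`) writes a manifest of MD5 checksums and
reproduces them exactly on re-run; reports regenerate byte-identically from
the same manifest.

## Known limitations

* Speckle synthesis is statistics-matched, not field-resolved; multi-pixel
  speckle grains and exposure-to-exposure correlation are absent.
* The MBLL chain omits scattering-change terms and oxygen-metabolism
  estimation.
* The transport model is a homogeneous slab with a simplified focused-beam
  launch and normal-incidence Fresnel handling only.
* The OCT phantom has no fringe/dispersion physics and its B-scan noise is
  additive Gaussian; segmentation quality on real angiograms will depend on
  speckle statistics the phantom does not reproduce.
* Register-level real-time control (laser/camera hardware) is out of scope;
  the guidance automaton consumes traces, not hardware events.
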
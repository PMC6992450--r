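Package: PhotoStroke
Title: Simulation and Analysis of Targeted Photothrombotic Stroke Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the optical workflow of awake-mouse targeted
    photothrombosis experiments. Synthesizes every input of the analysis
    chain with known ground truth (dynamic laser speckle stacks,
    multispectral reflectance movies, optical coherence tomography
    angiogram phantoms, cylinder-test paw-contact logs); computes spatial
    speckle contrast, blood flow index and relative cerebral blood flow
    with a closed-loop illumination-guidance state machine; inverts
    multispectral reflectance to oxy- and deoxyhemoglobin changes through
    the modified Beer-Lambert law with block-design trial averaging;
    provides Gaussian-beam closed forms and Monte Carlo photon transport
    for photoactivation dosimetry; builds angiograms from repeated B-scans,
    segments flowing capillaries and profiles radial ring densities; and
    scores forelimb-use asymmetry with longitudinal paired statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'PhotoStroke-package.R'
    'RcppExports.R'
    'behavior.R'
    'gen-angiogram.R'
    'gen-behavior.R'
    'gen-multispectral.R'
    'gen-speckle.R'
    'guidance.R'
    'io.R'
    'lsci.R'
    'mbll.R'
    'oct.R'
    'optics.R'
    'phantom.R'
    'pipeline.R'
    'speckle-theory.R'
    'transport.R'
    'utils.R'
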
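Package: smoothsolv
Title: Smooth, Differentiable Bulk-Solvent Models for Macromolecular
    Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuum bulk-solvent corrections for macromolecular
    diffraction built on Babinet's principle. Implements two smooth,
    coordinate-differentiable solute/solvent characteristic functions -- a
    thresholded atom-centered Gaussian mask and a cubic polynomial-switch
    mask -- alongside the classical binary probe/shrink reference mask.
    Provides direct-summation atomic structure factors, FFT mask structure
    factors, solvent scaling with k_s and B_s, a least-squares refinement
    target with analytic coordinate gradients propagated through the
    solvent mask, solvent-parameter optimization, finite-difference
    gradient verification, and synthetic toy-crystal fixtures, plus PDB,
    CCP4 map and reflection-file input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'cell.R'
    'formfactors.R'
    'crystal.R'
    'grid.R'
    'mask-gaussian.R'
    'mask-polynomial.R'
    'mask-binary.R'
    'scattering.R'
    'target.R'
    'optimize.R'
    'gradients.R'
    'scan.R'
    'fixtures.R'
    'io-pdb.R'
    'io-map.R'
    'io-reflections.R'
    'config.R'
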
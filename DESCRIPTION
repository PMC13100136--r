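Package: phicao
Title: Phase-Based Computational Adaptive Optics for 3D Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational adaptive optics for three-dimensional wide-field and
    structured-illumination fluorescence microscopy. Models aberrated pupil
    functions, point spread functions and optical transfer functions (split into
    modulation and phase transfer components), measures optical aberrations
    directly from a 3D image stack by phase-only Wiener deconvolution combined
    with a sharpness-metric search over Seidel and Zernike modes, and removes
    the measured aberrations by amplitude-and-phase Wiener deconvolution.
    Supports spatially varying (subregional) correction, a modulation-amplitude
    aberration metric for raw 3D structured-illumination stacks, synthetic
    phantom generation (points, beads, Bezier-curve fibers, raw SIM stacks)
    with Poisson noise, and TIFF/MRC stack input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
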
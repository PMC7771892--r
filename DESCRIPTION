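Package: fpmsda
Title: Structure-Dependent Amplification for Background Correction in
    Fourier Ptychographic Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for Fourier
    ptychographic microscopy (FPM) centred on structure-dependent
    amplification (SdA), a non-parametric background-correction and
    denoising scheme for darkfield frames. Provides a coherent forward
    model for LED-array illumination, Poisson-Gaussian sensor
    degradation, sequential Gauss-Newton phase retrieval with
    per-iteration stack substitution, the SdA pixel classification /
    amplification / suppression pipeline with its dual output stacks,
    reference global and rolling-ball background corrections, and an
    image-quality metric suite (SSIM, MSE, SNR, Michelson contrast,
    azimuthally averaged power spectra).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils-fft.R'
    'geometry.R'
    'fixtures.R'
    'forward.R'
    'stack.R'
    'sda.R'
    'baselines.R'
    'reconstruct.R'
    'postprocess.R'
    'metrics.R'
    'io.R'
    'experiment.R'
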
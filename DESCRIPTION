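Package: mdesim
Title: Spectrally Modulated Multidimensional Diffusion Encoding: Waveforms,
    Signal Prediction and Monte Carlo Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design and spectral analysis of gradient waveforms for
    multidimensional diffusion encoding (MDE) in diffusion MRI: isotropic
    encoding by magic-angle spinning of the q-vector, and spectrally tuned
    and detuned single-axis encodings derived from it. Predicts the
    diffusion-weighted signal of restricted (planar, cylindrical, spherical)
    and Gaussian compartments in the frequency domain from the dephasing
    power spectrum and closed-form diffusion spectra, cross-validates the
    predictions with a compiled random-walk Monte Carlo engine, and provides
    powder-average statistics, cumulant fits, synthetic multi-compartment
    phantoms, and the size and anisotropy subtraction contrasts obtained
    from the three encodings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
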
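Package: hyperdr
Title: Task-Driven Spectral Data Reduction for Hyperspectral Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Joint end-to-end training of a per-pixel linear spectral
    data-reduction subnetwork together with a segmentation convolutional
    neural network (mixed-scale dense or U-Net backbone), so that reduction
    of a hyperspectral cube to one or two channels preserves the spectral
    features relevant to the segmentation task. Includes simulators for
    attenuation-based hyperspectral X-ray projection data (cone-beam
    cylinder phantoms, Beer-Lambert transmission, K-edge attenuation
    spectra, Poisson noise, flatfield correction) and reflectance-based
    remote-sensing scenes (material disks, solar irradiance, water
    absorption bands, Gaussian noise), plus PCA, NMF and LDA baseline
    reducers fitted on subsampled pixels, training with ADAM and
    validation-based model selection, and average-class-accuracy
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    jsonlite,
    png,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
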
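Package: isfr
Title: Quantitative Reflectance Models for Single-Fiber and Imaging
    Single-Fiber Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modeling of single-fiber reflectance (SFR)
    and imaging single-fiber reflectance (iSFR) spectroscopy of turbid media
    such as biological tissue. Provides analytic scattering phase-function
    families (two-term Henyey-Greenstein, modified Henyey-Greenstein,
    Reynolds-McCormick) with their angular moments and the semi-ballistic
    descriptor p_sb; an absorption-free (white) Monte Carlo photon-transport
    engine for semi-infinite media with numerical-aperture launch and Fresnel
    boundary handling; a single-integral approximation that converts
    point-source photon records into reflectance for arbitrary spot diameters
    and absorption coefficients; the semi-empirical subdiffuse reflectance
    model with shipped fitted parameters; the two-step relative least-squares
    parameter fit; wavelength-parameterized tissue spectra with hemoglobin
    absorption; and multistart nonlinear least-squares retrieval of optical
    properties from noisy reflectance spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
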
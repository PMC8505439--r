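Package: VortexPSF
Title: Simultaneous 3D Localization and Dipole Orientation Estimation with the
    Vortex Point Spread Function
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Vectorial point-spread-function (PSF) modeling and maximum
    likelihood fitting for single-molecule localization microscopy with a
    vortex (spiral) phase mask in the emission path. Fits the 3D position,
    azimuthal and polar dipole orientation, and degree of rotational
    constraint of single emitters from individual 2D camera frames, using a
    fully vectorial dipole image formation model that includes supercritical
    angle fluorescence, Fresnel transmission through the sample stack, and
    Zernike aberrations. Provides Cramer-Rao lower bound analysis,
    Poisson maximum likelihood fitting with the standard acceptance filters,
    field-dependent aberration calibration via Nodal Aberration Theory,
    a frame-to-localization pipeline with linking and fine drift correction,
    orientation analyses along DNA strands (wobble-cone conversion, strand
    axis splines, relative azimuth, binned autocorrelation periodicity), and
    seeded synthetic-data generators and benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
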
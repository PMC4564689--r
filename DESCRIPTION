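Package: spasim
Title: Single-Particle Averaging of Two-Color Structured-Illumination Volumes
Version: 0.1.0
Authors@R: person("spasim", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for single-particle averaging of two-color 3D
    structured-illumination microscopy (SIM) volumes of diffraction-limited
    particles such as the yeast spindle pole body. Provides semi-automated
    particle detection on sum projections, constrained dual 3D Gaussian
    fitting by box-constrained nonlinear least squares, sub-pixel realignment
    of particles onto a common mother-satellite/pole frame by trilinear
    interpolation, accumulation of dual-color probability maps, multi-Gaussian
    profile decomposition with Monte Carlo uncertainty estimates, geometry
    summaries (separations, bend angles, intensity ratios, contour outlines),
    a ground-truthed synthetic scene generator, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
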
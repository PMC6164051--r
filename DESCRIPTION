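Package: cyldiff
Title: Water Vapor Diffusivity in Polydisperse Cylindrical Particle Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of apparent water-vapor diffusivity in micrometric
    cylindrical particles (e.g. cellulose powders) from quartz crystal
    microbalance (QCM) sorption kinetics. Builds two-dimensional particle size
    distributions (length x diameter) from image-analysis tables, evaluates
    the analytical Fickian fractional-uptake series for finite cylinders and
    for heterogeneous cylinder populations structured in volume-weighted size
    classes, converts frequency traces to sorbed mass via the Sauerbrey
    equation, and identifies diffusivity and equilibrium mass per relative
    humidity step by bounded nonlinear least squares. Includes an axisymmetric
    finite-difference solver of the underlying diffusion problem for
    validating the series solution, and a synthetic-data generator (correlated
    lognormal mixture populations, simulated multi-step QCM traces) so the
    full pipeline can be exercised and benchmarked without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
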
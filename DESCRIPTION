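Package: perizone
Title: Peritumoral Edema Zonation and Diffusion Microstructure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying microstructural gradients in the peritumoral
    edema of brain tumors with diffusion MRI. Simulates two-shell
    diffusion-weighted phantoms with a contrast-enhancing core and an edema
    shell carrying known stick-zeppelin-ball microstructure, fits the
    diffusion tensor (FA, MD) by ordinary log-linear regression, estimates
    three-compartment microstructure parameters (intra-axonal and free-water
    volume fractions, axial intra- and extra-axonal diffusivities) from
    rotation-invariant spherical signal features, parcellates the edema into
    equal-volume inner, middle and outer zones by Euclidean expansion from
    the core outline, and runs normality-gated within- and between-group
    zone-gradient statistics including ANCOVA controlling for edema volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
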
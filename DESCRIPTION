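Package: ferrodyn
Title: Feedback Dynamics of Cell Proliferation, Lipid ROS, and Ferroptosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the feedback loop between cell-population
    growth, lipid reactive oxygen species (ROS), and ferroptotic cell death.
    Implements a two-variable ordinary differential equation model (population
    confluence and per-cell lipid ROS), fixed-point enumeration and stability
    classification, basin-of-attraction maps over initial states, weighted
    least-squares estimation of model parameters from live-cell imaging time
    courses, the signal transforms used to turn raw imaging channels into
    model observables (oxidized/reduced reporter ratios, dead-cell
    normalisation, dead-cell mask exclusion), and a fully seeded synthetic-data
    generator emulating density, GPX4-inhibition, growth-space, and
    glucose/galactose experimental designs, including rendered microscopy-like
    image frames with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
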
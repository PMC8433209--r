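Package: cryoperm
Title: Oocyte Membrane Permeability from Microfluidic Perfusion Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for estimating oocyte membrane permeability
    (hydraulic conductivity Lp and cryoprotectant permeability Ps) from
    micrograph-derived volume trajectories recorded during cryoprotectant
    perfusion in a multichannel microfluidic chip. Implements the
    two-parameter membrane transport model and its nonlinear least-squares
    fit, a parabolized advection-diffusion solver for the serpentine
    co-flow mixer with Stokes-Einstein diffusivities, classical and
    compact encoder-decoder (U-Net style) oocyte segmentation with
    equivalent-sphere volume extraction, and a fully seeded synthetic
    micrograph generator so the complete image-to-parameter chain can be
    verified by parameter recovery without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
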
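Package: thermolip
Title: Heat Transport and Cholesterol Thermodiffusion Analysis for Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for boundary-driven nonequilibrium molecular
    dynamics (NEMD) simulations of lipid bilayers under thermal gradients.
    Computes slab-binned temperature and density profiles, steady-state heat
    flux from thermostat energy ledgers, thermal conductivity via Fourier's
    law and interfacial thermal conductance; cholesterol leaflet-partitioning
    time series, two-state flip-flop kinetics, steady-state asymmetry and
    Soret coefficients; two-dimensional free-energy landscapes of cholesterol
    position and tilt with minima detection and one-dimensional projections;
    and membrane-structure metrics (chain order parameter, area per lipid,
    in-plane radial distribution functions, melting-temperature extraction
    from hysteresis cycles). Every analysis stage is paired with a synthetic
    generator of its inputs with known ground truth, including an overdamped
    Langevin simulator of thermophoresis in a double-well potential, so the
    full pipeline is verifiable without molecular-dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
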
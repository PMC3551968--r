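Package: rsetsim
Title: Spiking Ensembles of Single-Electron Transistor Relaxation Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed continuum-Monte Carlo simulation of ensembles of
    resistance-coupled single-electron transistors (R-SETs), threshold-potential
    nanostructures that behave as integrate-and-fire relaxation oscillators.
    Supports homogeneous and heterogeneous ensembles (uniform spread of
    capacitance and charging resistance), grey-image processing by rate and
    rank-order spike coding, reconstruction of time-dependent analog signals
    from binned ensemble spike counts, and synchronization of resistively
    coupled ensembles measured by the complex (Kuramoto) order parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
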
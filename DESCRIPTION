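Package: magsort
Title: Simulation of Strip-Array Immunomagnetic Cell Fractionation in Microchannels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale simulator for microfluidic immunomagnetic cell sorting on
    soft-magnetic strip arrays. Computes the sculpted magnetic field of a
    magnetized strip array in a laterally decaying background field, the
    magnetophoretic force on bead-labelled cells, laminar channel flow with
    sheath-flow sample confinement, coupled drag/friction single-cell
    trajectories with capture detection, and population-level fractionation of
    synthetic cell populations into High/Medium/Low/Negative bead-load
    subtypes, with per-strip capture histograms and recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
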
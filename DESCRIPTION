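Package: biodeg
Title: Biodegradation Assay Analytics for Plastics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for closed-bottle plastic biodegradation
    assays. Computes Buswell stoichiometry, theoretical biochemical
    methane potential (BMP) and theoretical oxygen demand (ThOD) from
    polymer repeat-unit formulas; converts periodic headspace gas
    measurements into blank-corrected cumulative methane-production or
    oxygen-consumption curves at STP (including air re-flush accounting
    for aerobic respirometry); combines both into percent-biodegradation
    results with inoculum validation against the cellulose-control
    criterion; summarizes amplicon taxon-count tables into
    relative-abundance profiles with a display threshold; and generates
    fully synthetic assay datasets with known ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
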
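Package: nannoproxy
Title: Reconstructing Coccolithophore Physiology and Calcite Production
    from Sedimentary Coccolith Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to turn coccolith census counts and per-coccolith
    morphometry from surface sediments into absolute abundances,
    calcification-intensity indices (size-normalized thickness, elliptical
    shape factor, morphometric PIC/POC), relative growth-rate estimates,
    group-specific calcite production per gram of sediment, and the
    latitudinal boundary between low and high PIC/POC dominated calcite
    production. Includes a carbonate-system speciation solver for derived
    environmental state ([CO2], [HCO3-], [CO3^2-], pH, calcite saturation),
    a correlation screen against surface-ocean environmental fields, and a
    calibrated synthetic meridional-transect generator so the whole
    pipeline is testable end to end against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
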
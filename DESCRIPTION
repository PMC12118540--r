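Package: coastspray
Title: Tracer-Based Attribution of Wastewater Pollutants in Coastal Sea
    Spray Aerosol
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for linking wastewater-derived chemical
    pollutants measured in coastal waters and aerosols. Provides a seeded
    synthetic campaign generator (river flow, rain, wind, water and aerosol
    concentrations with detection-limit censoring), external-calibration
    quantification with blank-based QA/QC, two sea spray aerosol mass-flux
    parameterizations (surf-zone and wind/sea-surface-temperature), rain-event
    detection with pre/post window statistics, sewage-tracer regressions and
    Mann-Whitney spatial comparisons, aerosolization-factor and bubble
    scavenging analyses, and compartmental river-to-ocean, ocean-to-air,
    onshore-transfer and inhalation-exposure estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
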
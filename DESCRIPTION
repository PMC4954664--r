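Package: aukforage
Title: Foraging Ecology Pipeline for a Central-Place Arctic Seabird
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable analysis pipeline for GPS, time-depth-recorder and
    zooplankton data from chick-rearing little auks (Alle alle). Classifies
    GPS fixes into travelling versus foraging/resting by a speed threshold,
    segments tracks into colony-to-colony trips and computes trip metrics;
    estimates kernel utilization distributions of foraging positions, their
    volume contours and percentage overlap with a bathymetric shelf-break
    band; calibrates and summarises dive records; computes diet composition
    tables, a linear food selection index with parametric bootstrap,
    Bray-Curtis/Ward community clustering and per-habitat density tests;
    fits random-intercept chick-growth models with AIC selection and an
    adult body-condition index; and summarises regional sea-ice
    concentration series with a linear trend test. A synthetic-data module
    generates every input the pipeline consumes, with embedded ground
    truth, so all stages run end-to-end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    lme4,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
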
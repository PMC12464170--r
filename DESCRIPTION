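Package: airsound
Title: Joint Air Pollution and Sound Exposure Campaign Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for processing urban air-pollution and sound monitoring
    campaigns that combine a small number of continuously monitored fixed
    sites with many short rotating-site deployments. Implements gravimetric
    filter processing with field-blank correction, black carbon
    quantification from optical attenuation, season-specific linear
    calibration of low-cost light-scattering PM2.5 sensors against
    co-located gravimetric references, weekly temporal adjustment factors
    that make rotating-site measurements comparable across a season,
    energy-based sound metrics (equivalent continuous level and the
    intermittency ratio), land-use exposure summaries, and bivariate
    tertile hotspot classification. Ships a synthetic two-season campaign
    generator so the full pipeline is testable end to end without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    sandwich,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
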
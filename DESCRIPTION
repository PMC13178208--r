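Package: n2odyn
Title: Dynamic Emission-Factor Projection of Agricultural Soil N2O
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Projects direct nitrous oxide (N2O) emissions from fertilized
    agricultural soils over 2010-2050 under combined nitrogen-policy and
    climate scenarios, contrasting a dynamic, environment-dependent emission
    factor (EF) learned by a statistical emulator with the static IPCC
    Tier-1 factor of 1 percent.  Includes a fully synthetic world generator
    (grid domain, soils, climate ensemble with biased pseudo-GCM members,
    skewed baseline fertilizer, and a closed-form "true" EF response
    surface), delta-method climate bias correction, nitrogen-use-efficiency
    driven fertilizer scenarios, ensemble percentile summaries,
    reduction-target timelines, and hotspot-prioritized
    nitrification-inhibitor mitigation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
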
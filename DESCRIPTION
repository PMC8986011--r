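Package: tickhab
Title: Habitat Use, Preference and Niche Breadth for Tick Field Surveys
Version: 0.1.0
Authors@R: person("Matepantano", "Analytics", email = "dev@example.org",
    role = c("aut", "cre"))
Description: Use/availability analysis for seasonal capture surveys of
    free-living tick stages sampled across discrete habitats. Computes
    availability and use proportions, sample-adequacy diagnostics (G-test,
    Pearson chi-square, Cherry criterion), five habitat-preference indices
    (Duncan, Ivlev electivity, Bailey simultaneous confidence intervals,
    Manly alpha under constant resources, Jacobs' D) with their decision
    rules and a cross-index consensus call, five niche-breadth statistics
    (Shannon and Levins families, Ivlev amplitude), and a seasonal
    growth-rate chain. Ships a multinomial survey simulator with a
    parameter-recovery harness so the whole pipeline is testable without
    field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
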
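Package: sociodiag
Title: Social Network Diagnostics for Small-Group Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes whole-network and individual sociometric diagnostics
    (density, reciprocity, dyad census, centralization, transitivity,
    compactness, isolates, subgroups) for small intervention groups measured
    with roster-based name generators, compares them to pre-registered
    thresholds, and renders participant-specific action reports for the group
    leader. Includes a node-resampling bootstrap test for between-wave density
    change that respects the dyadic non-independence of network data,
    Perceived Cohesion Scale scoring and psychometrics, and synthetic-data
    generators (exact dyad-census networks, two-wave evolution, Likert
    responses) so the whole pipeline is testable without any field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
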
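Package: mutoverlay
Title: Overlay Visualization of Recurrent Somatic Mutation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses protein-level somatic mutation annotations (the COSMIC
    "Mutation AA" dialect of HGVS) into amino-acid positions, aggregates
    per-gene recurrence counts separately for a reference and a test
    mutation set, and renders overlay plots in which a small test cohort is
    superimposed on a large reference compendium so that hotspot sites and
    hotspot regions are visually identifiable.  Includes region drill-down
    export of the underlying records, a synthetic fixture generator with
    planted hotspots, and a command-line workflow (prepare, merge, plot,
    query, simulate).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
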
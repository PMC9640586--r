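Package: sapsource
Title: Source-Area Profiling and Molecular Surveillance for Sap-Beetle Invasions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for reconstructing the introduction area of an
    invasive sap beetle (Nitidulidae) from infested-site records and for
    summarising its molecular and field surveillance data. Implements
    distance-decay (Dragnet-style) geographic profiling on a lon/lat grid with
    bootstrap aggregation of score surfaces and an elevation mask, coalescent
    haplotype sampling-sufficiency and haplotype-detection sample-size
    formulas, uncorrected p-distance matrices within and between sequence
    groups with site-bootstrap standard errors, fruit-level damage-attribution
    rules with site and category summaries, and seeded synthetic-data
    generators (occurrences, elevation rasters, alignments, haplotype samples,
    fruit records) so the whole pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
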
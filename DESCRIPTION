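Package: strauth
Title: Short Tandem Repeat Profile Authentication for Mouse Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for authenticating mouse cell lines by short tandem repeat
    (STR) profiling over the 19-marker CellCheck mouse panel. Provides a
    genotype model for microsatellite alleles (including microvariants such as
    20.3), percent-match statistics (Tanabe and both Masters variants) over
    selectable marker subsets, ranked database search with score and
    minimum-marker filters, threshold-based allele calling from
    electropherogram peak tables, and a synthetic profile/peak-table generator
    for modelling genetic drift and cross-contamination. Ships the published
    reference profile of the Col-GFP HSC hepatic stellate cell line and its
    closest database matches as plain-text fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
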
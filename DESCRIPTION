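Package: chelaweather
Title: Chelator-Promoted Basalt Weathering, Siderophore Omics and
    Carbon-Dioxide-Removal Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for chelator-enhanced rock weathering
    studies. Quantifies siderophore biosynthesis genes from shotgun
    metagenome and metatranscriptome homology hit tables
    (length-normalized counts scaled by the single-copy marker rpoA),
    calibrates and inverts chrome azurol S (CAS) and bioassay standard
    curves, turns solution chemistry from basalt dissolution experiments
    into element release rates with AIC-selected concentration-response
    models, resolves pH and dissolved inorganic carbon into bicarbonate
    for alkalinity-based carbon-dioxide-removal accounting, computes the
    soil-microcosm CDR-gain statistic from exchangeable-cation tables,
    and implements a techno-economic model of potassium-EDDHA amendment
    with soil-moisture uncertainty propagation. Includes a synthetic-data
    generator with planted ground-truth parameters so every stage is
    testable without raw sequencing or ICP-MS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
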
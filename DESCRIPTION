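Package: protrend
Title: Trend Statistics for Protein Alignments Across Ordered Phenotypic
    Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical detection and visualization of compositional,
    substitutional and physicochemical trends across ordered phenotypic
    groups (for example mesophile to psychrophile) in multiple protein
    alignments, optionally constrained by secondary structure and solvent
    accessibility.  Implements tie-corrected and blocked (cumulative)
    Mann-Kendall trend tests, mid-p Fisher exact tests on substitution-pair
    contingency tables, Jones-method sequence pairing and substitution-pair
    matrices, stratified dummy-variable regression of mean physicochemical
    properties, and Benjamini-Yekutieli false discovery rate control, plus
    a deterministic generator of synthetic annotated alignments for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    ggplot2,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
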
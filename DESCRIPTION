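Package: nanopep
Title: Design and Dosimetry Toolkit for Peptide-Gold-Nanoparticle Nanovaccines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for designing and analysing peptide-functionalized gold
    nanoparticle (p-AuNP) vaccine candidates: annotation of modular
    immunogenic peptide constructs (anchor/spacer/epitope/cell-penetrating
    regions) and their charge composition, protease cleavage-site scanning
    with an eight-subsite (P4-P4') specificity matrix including fragment
    enumeration and epitope-release checks, sphere-based nanoparticle
    dosimetry (volume, surface area, gold-atom content, size-dependent
    extinction, Beer-Lambert concentration) and peptide conjugation
    planning, MHC allele-frequency population coverage, and assay
    post-processing (control normalization, four-parameter logistic IC50
    fitting, survival-normalized enzymatic activity, charge-activity
    summaries). A seeded synthetic-data module generates every input the
    pipeline consumes so all stages run without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
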
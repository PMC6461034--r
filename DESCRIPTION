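Package: inka
Title: Integrative Inferred Kinase Activity Scoring from Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers hyperactive protein kinases in single biological samples
    from quantified phosphoproteomics data. Phosphopeptide and phosphosite
    tables (MaxQuant dialect) are filtered to class I sites, merged, and scored
    against kinase-substrate knowledgebases to yield per-kinase INKA scores:
    the geometric mean of kinase-centric evidence (phosphopeptides on the
    kinase itself, including activation-loop sites) and substrate-centric
    evidence (phosphosites attributed to the kinase through curated or
    predicted kinase-substrate relations). Includes permutation-based
    significance assessment, kinase-substrate network construction and export,
    a kinase impact score linking activity rankings to drug-efficacy data, and
    a synthetic-data generator with planted driver kinases for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
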
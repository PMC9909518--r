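Package: atcmapr
Title: Assessing and Improving the Structuredness of Free-Text Drug
    Prescriptions via ATC Code Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring and improving the structuredness of
    electronic-health-record drug prescription tables in which medications
    were entered either as catalog picks (carrying a WHO ATC level-5 code)
    or as free text. Free-text entries are mapped to ATC codes by a cascade
    of three algorithms: whole-token ingredient-name matching, whole-token
    product-name matching, and fuzzy similarity matching built on a native
    token-set ratio over an insertion/deletion edit distance. Inter-algorithm
    concordance and similarity-score patterns classify result reliability,
    a validation-workbook round trip supports manual expert review, and
    final reports summarise structuredness by ATC level-1 group and by
    level-5 ingredient. A seeded synthetic generator produces drug catalogs
    and prescription tables with known ground truth for end-to-end testing.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
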
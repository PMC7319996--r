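Package: tissuedecoder
Title: Cell-Type Deconvolution of Bulk Adipose Tissue Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the cell-type composition of bulk tissue gene expression
    profiles by nu-support-vector regression against a cell-type signature
    matrix. Builds signature matrices from labeled reference expression data by
    differential marker selection and a condition-number-minimizing sweep over
    marker-set sizes; scores candidate cell-type markers with primary
    (expression minus the maximum over other cell types) and secondary
    (expression minus the mean over other cell types) specificity criteria;
    converts literature cell-count reports in heterogeneous units to percent of
    total cells; associates estimated fractions with phenotypes via Wilcoxon
    and Spearman permutation tests with Benjamini-Hochberg correction; and
    ships a synthetic-data generator so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
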
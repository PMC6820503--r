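Package: cytoboot
Title: Donor-Aware Bootstrap Analysis of Mass Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end statistical analysis of per-cell mass cytometry (CyTOF)
    data with donors as the unit of inference. Provides reading and writing of
    FCS 3.0/3.1 and delimited cell tables, a synthetic study generator with
    donor random effects and zero-inflated intensities, boolean threshold
    gating of NK cell subsets, cell-level logistic regression with
    donor-stratified bootstrap confidence intervals for marker effects,
    Fisher linear discriminant analysis of donor marker profiles, and exact
    Mann-Whitney and Wilcoxon signed-rank comparisons of gated frequencies,
    orchestrated by a seeded, manifest-producing pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    stats,
    tools,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
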
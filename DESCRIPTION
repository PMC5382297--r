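Package: mixge
Title: Set-Based Mixed-Effect Score Tests for Gene-Environment Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Set-based testing of gene-environment (GxE) interaction on
    quantitative or binary phenotypes. A variant set is tested jointly for
    interaction with a single environmental exposure by combining two
    independent score statistics: a fixed-effect (burden-type) interaction
    score, referred to a chi-square distribution, and a variance-component
    (SKAT-type) interaction score whose null law is a mixture of chi-squares
    evaluated by moment matching. The two p-values are combined by the Fisher
    or Tippett rule. Includes a Hardy-Weinberg simulation engine for type-I
    error and power studies, Storey q-value false discovery rate control, a
    vectorized voxelwise driver for imaging phenotypes, genotype input from
    VCF or delimited text, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    RNifti
Config/testthat/edition: 3
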
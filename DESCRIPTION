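Package: crossferome
Title: Cross-Species Comparison of Type I Interferon Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of type I interferon (IFN)
    transcriptional responses across vertebrate species. Starting from
    per-species replicated expression counts and an orthology map, the
    package calls interferon-stimulated genes (ISGs) and interferon-repressed
    genes (IRGs) at a Benjamini-Hochberg false discovery rate, merges calls
    onto orthologous gene clusters with paralog averaging, bins orthogroups
    by the number of responding species, extracts core (all-species and
    mammal-only) ISG sets, and computes the comparative statistics used in
    multispecies interferome studies: pairwise interferome similarity,
    principal component analysis of shared one-to-one orthologs, resampling
    enrichment of antiviral gene panels, gene-family expansion ratios with
    resampled backgrounds, dN/dS distribution contrasts, basal-expression
    contrasts, and median-normalised homology hit counts. A negative-binomial
    simulator with orthology structure and known ground truth supports
    calibration and power analysis.
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
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
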
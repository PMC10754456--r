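Package: clonechron
Title: Time-Resolved Analysis of Clonally Evolving Genomes from Allele-Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the temporal dynamics of clonally expanding
    populations (tumors, clonal animal lineages) from somatic variant
    allele frequencies. Builds mutation-accumulation curves M(1/f) with
    bootstrap confidence bands, segments them into evolutionary phases
    with Davies' significance test and k-fold cross-validation, computes
    longitudinal dN/dS against a codon-opportunity baseline, fits
    non-negative exposures of 96-channel single-base-substitution
    signatures along the frequency axis, converts clock-like exposures
    into a time course, propagates time from a recurrent to a primary
    tumor, estimates the tumor-cell survival ratio at resection, derives
    expansion profiles, and classifies them by k-means with
    Calinski-Harabasz model selection. Includes a Galton-Watson style
    clonal-expansion simulator with full ground truth for validation, and
    a trio-based per-year mutation-rate estimator with a three-component
    uncertainty model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR
Config/testthat/edition: 3
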
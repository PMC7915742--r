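Package: petrepeat
Title: Test-Retest Repeatability Analysis for PET Radiomics Features
Version: 0.1.0
Authors@R: person("petrepeat", "maintainers", email = "petrepeat@example.org",
    role = c("aut", "cre"))
Description: Tools to assess the test-retest repeatability of radiomics
    features from amino-acid PET imaging of brain tumors. Simulates
    synthetic PET cohorts with independent half-count ("odd/even event")
    image pairs, segments tumor and background volumes-of-interest by
    tumor-to-brain-ratio thresholding, computes a 1,302-feature radiomics
    bank (first-order and gray-level texture families on original,
    wavelet- and Laplacian-of-Gaussian-filtered images), scores each
    feature with the two-way absolute-agreement single-measure intraclass
    correlation coefficient and a confidence-interval band classification,
    and clusters subjects on the repeatable feature subset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
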
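Package: capragen
Title: Multibreed Genomic Prediction for Dairy Goat Lactation Traits
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-trait genetic evaluation of multibreed dairy goat herds by
    pedigree-based BLUP and by single-step BayesC Bayesian marker regression.
    Provides pedigree algebra (numerator relationship matrix, its sparse
    inverse and genotyped/non-genotyped partitions, breed composition and
    general heterosis), phenotype editing and SNP quality control, Henderson's
    mixed model equations with prediction error variances, a Gibbs sampler for
    the single-step BayesC model with pedigree-imputed marker covariates and
    breed-specific J covariates, a pedigree-masking validation protocol with
    accuracy and genomic-inflation diagnostics, and a synthetic multibreed herd
    generator with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
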
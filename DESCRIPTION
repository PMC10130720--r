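Package: wildqg
Title: Quantitative Genetics of Floral Traits in Wild Plant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis workflow for estimating the evolutionary potential
    of floral traits measured on wild plants: SNP quality control and
    genome-wide realized relatedness (VanRaden), Bayesian animal models
    fitted by a blocked Gibbs sampler to partition additive genetic, site,
    permanent-environment and residual variance (heritability, mean
    standardized evolvability, genetic correlation, DIC model comparison),
    nonparametric selection differentials and gradients from binomial
    fitness surfaces with bootstrap inference, GREML-style power
    calculations, and a synthetic-study generator with known ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
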
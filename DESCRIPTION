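Package: admixpca
Title: PCA Pre-Processing, Diagnostics, and Collider Bias in Admixed-Population GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how principal-component adjustment for
    population structure behaves in genome-wide association studies of
    admixed populations. Provides a synthetic admixed-cohort generator
    (heterogeneous admixture proportions, local-ancestry blocks,
    ancestry-differentiated allele frequencies, injectable localized
    linkage-disequilibrium features), pre-PCA variant filtering (bundled
    high-LD region exclusion list, windowed r-squared pruning, minor allele
    frequency filtering), PCA of standardized genotypes with SNP-loading and
    PC-genotype correlation diagnostics, a marginal-regression GWAS engine
    with chromosome-level spurious-association counting and genomic-control
    lambda, analytic expected effect-size estimates under each covariate
    adjustment strategy (including collider bias from extraneous
    components), and orchestration of replicate simulation designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
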
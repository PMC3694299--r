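Package: plex8
Title: Eye- and Skin-Color Prediction from an 8-SNP Forensic Panel
Version: 1.0.0
Authors@R:
    person("OCME", "Phenotyping", email = "phenotyping@example.org",
           role = c("aut", "cre"))
Description: Rule-based prediction of human eye color (brown, green, blue,
    not-blue, not-brown) and skin color (light, not-dark, not-light) from
    genotypes at eight pigmentation SNPs (rs12913832, rs1545397, rs16891982,
    rs1426654, rs885479, rs6119471, rs12203592, rs12896399). Implements the
    two-step eye-color decision procedure and the homozygote-elimination
    skin-color predictor, reads genotypes from VCF or TSV, evaluates
    predictions against binned phenotypes with population-stratified error
    and call rates, ships the published training (n = 803) and test
    (n = 212) outcome tables as machine-readable fixtures, provides the
    contingency-table statistics used for SNP selection (chi-square test of
    independence, Cramer's V, Cohen's kappa, pooled two-proportion z-test),
    and generates synthetic Hardy-Weinberg cohorts with configurable
    population structure and genotype-phenotype discordance for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
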
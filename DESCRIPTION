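Package: decon2
Title: Cell-Type Deconvolution of Bulk Blood Expression and eQTL Effects
Version: 0.1.0
Authors@R:
    person("Decon2", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with heterogeneous bulk blood RNA-seq.
    Decon-cell learns sparse elastic-net signature-gene models that predict
    circulating immune-cell proportions from bulk expression, with repeated
    cross-validation to define predictable cell types and stable signature
    genes. Decon-eQTL decomposes bulk cis-eQTL effects into cell-type
    interaction (CTi) eQTLs by fitting a non-negative least squares model of
    per-cell-type expression with genotype-by-proportion interaction terms, a
    restricted genotype-encoding search, nested-model ANOVA tests and
    per-cell-type FDR control. Includes expression normalization (TMM,
    covariate correction), a minimal cis-eQTL mapper, a single-cell-type
    interaction comparator model, validation statistics (allelic concordance,
    Fisher enrichment, effect-size tests), a fully seeded synthetic-data
    generator with exported ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
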
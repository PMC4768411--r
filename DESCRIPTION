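Package: mdfdr
Title: Mixed-Directional False Discovery Rate Control for Many-to-One
    Comparisons
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a general three-step procedure that controls the
    mixed directional false discovery rate (mdFDR) when comparing several
    experimental groups against a common reference group across thousands
    of features, as arises in gene expression studies ordered by tumor
    size or dose. Features are first screened with a per-feature global
    p-value and selected by the Benjamini-Hochberg step-up rule; pairwise
    comparisons within selected features are then tested at a
    data-dependent level with a mixed-directional familywise error
    controlling procedure, and directions (up/down) are assigned by the
    sign of the test statistic. The default instantiation uses Dunnett's
    many-to-one test: the screening p-value is the tail probability of
    the maximum absolute component of an equicorrelated multivariate t
    vector, computed by deterministic two-dimensional Gauss-Legendre
    quadrature. Holm, Hochberg and Bonferroni step procedures and the
    Bonferroni-screening comparator are provided, together with a
    simulation framework that estimates mdFDR and average power under
    independent, within-sample-correlated and within-feature-correlated
    Gaussian error models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
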
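Package: ocmann
Title: One-Carbon Metabolism Case-Control Analysis with Evolutionary
    Variable Selection and Auto-Contractive Maps
Version: 0.1.0
Authors@R:
    person("OCM", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for case-control analysis of one-carbon (folate)
    metabolism cohorts: one-hot coding of biallelic polymorphism genotypes
    and min-max scaling of biomarkers into design matrices; a synthetic
    cohort generator parameterized by published per-group genotype
    frequencies and biomarker means with confidence intervals; a native
    K-nearest-neighbour classifier with k-fold, random-split and
    two-subset validation protocols; an evolutionary wrapper (TWIST-style)
    that jointly selects input variables and an optimally balanced record
    bipartition by blind two-way KNN accuracy; and an Auto-Contractive
    Map whose converged weights, converted to distances and filtered by a
    minimum spanning tree, yield a semantic connectivity map of variable
    associations with hubs and 0-1 link strengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
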
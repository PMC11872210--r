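Package: traitscape
Title: Multivariate Trait Plasticity and Clonal Genotype Diversity in Spartina
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for a greenhouse drought-by-CO2 experiment on
    hybrid and allopolyploid Spartina cytotypes, and for SSR (microsatellite)
    multilocus genotype surveys of their salt-marsh populations. Implements
    multilocus genotype calling from per-locus allele-size sets, genotype
    frequency tables, allelic dissimilarity matrices and tie-retaining minimum
    spanning networks; regularized iterative PCA imputation of missing trait
    values and the trait-scape PCA ordination; Euclidean-distance plasticity
    indices (the multivariate plasticity index MVPi and a centroid-based
    trait-variation index); Box-Cox transformation, full-factorial three-way
    ANOVA with Tukey HSD post hoc tests and assumption checks; a leaf-area
    allometry model; and a seeded synthetic-data generator reproducing the
    experiment's full-factorial design so every stage is testable without the
    deposited raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    car,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
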
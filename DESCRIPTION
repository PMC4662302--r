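Package: rarecomp
Title: Comparative Ecological Genetics of Rare and Widespread Congeners
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for comparing quantitative-genetic and
    molecular diversity between rare and widespread congeneric species.
    Provides simulation of codominant genotypes under the Balding-Nichols
    island model with selfing, null alleles and missing calls; Nei
    gene-diversity statistics (Ho, Hs, Ht, Dst, Fst, Fis, effective allele
    numbers) with a rarefy-then-bootstrap confidence-interval procedure;
    composite-phenotype construction by weighted principal components and
    nested random-effects variance partitioning into Qst and broad-sense
    heritability with parametric bootstrap; growth-rate plasticity breeding
    values in two environments; population genetic graphs pruned by
    edge-exclusion deviance with community modularity; and cross-species
    synthesis: grid-cell range sizes, Fst:Qst drift diagnostics, spatially
    explicit population subsampling, and regressions of species means on
    log10 range size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    lme4,
    igraph,
    MASS,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
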
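Package: thromboSig
Title: Stable-Isotope Biosignatures and Comparative Microbiome Analytics
    for Thrombolite-Forming Microbial Mats
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for studies that compare lithifying
    (thrombolite-associated) and non-lithifying microbial mats. One half is
    a carbonate-system stable-isotope model: dissolved inorganic carbon is
    speciated from pH and temperature, carbon-isotope mass balance among
    CO2(aq), HCO3- and CO3(2-) yields the bicarbonate delta-13C, and the
    aragonite-bicarbonate equilibrium fractionation predicts the theoretical
    equilibrium delta-13C of aragonite, against which measured carbonate is
    scored as photoautotrophic or heterotrophic biosignature offsets; a
    conductivity-salinity power law for Australian salt lakes estimates TDS.
    The other half operates on feature-by-sample count tables: depth
    normalization, analytic rarefaction, Bray-Curtis dissimilarity, principal
    coordinates analysis, UPGMA clustering, PERMANOVA, and a negative-binomial
    Wald differential-abundance stage with Benjamini-Hochberg correction and
    effect-size/abundance enrichment filters. Seeded synthetic-data generators
    with known truth make every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Metagenomics, Microbiome, DifferentialExpression, Sequencing
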
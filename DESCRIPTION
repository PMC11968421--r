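Package: dietbarcode
Title: Stomach-Content DNA-Metabarcoding Diet Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diet analysis of stomach-content DNA-metabarcoding data from an
    OTU-by-sample read-count table, taxonomy, sample metadata and an optional
    phylogeny. Computes frequency of occurrence (FO) and relative read
    abundance (RRA) diet profiles with food-category aggregation and
    Costello-style feeding-strategy classification; per-sample trophic
    diversity (Shannon-Wiener H', Pielou J, Levins niche breadth B) and
    pairwise Schoener diet overlap; community structure via Bray-Curtis and
    weighted UniFrac distances, NMDS, PERMANOVA, Kruskal-Wallis with compact
    letter displays, and an LDA effect-size (LEfSe-style) biomarker screen;
    and environmental-driver analyses (VIF collinearity screening, Spearman
    correlations, standardized multiple regression, binomial and gamma GLMs,
    Hellinger transformation, DCA gradient-length model choice, RDA with
    permutation tests and envfit, and Mantel tests against great-circle
    geographic distance). A Dirichlet-multinomial generator simulates grouped
    stomach-content datasets with environmental effects so the full pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    MASS,
    geosphere,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
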
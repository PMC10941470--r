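Package: isogloss
Title: Isogloss Mapping and Spatial Association of Plant Folk Nomenclature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dialectometric analysis of plant folk nomenclature. Computes a
    flora-corrected shared-name dissimilarity index and the Jaccard distance
    on vernacular name inventories, builds Ward-linkage dendrograms and prunes
    them into isogloss partitions, identifies indicator names for partition
    groups by permutation-tested indicator-value analysis, and quantifies the
    spatial association of partition maps with thematic layers via the
    entropy-based V-measure (homogeneity and completeness) and the
    factor-detector q-statistic. Includes a synthetic-data generator with
    known ground truth for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    stringi,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust
Config/testthat/edition: 3
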
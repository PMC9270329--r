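Package: histoml
Title: Ontology-Based Representation and Quantification of Histopathological Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An implementation of the HistoML Level 1 representation language
    for multi-scale histopathological features in whole-slide images.
    Provides the Level 1 ontology schema (Entity/Utility/Data roots,
    physical entities, phenotypes, attributes and quantifications), an
    in-memory document model with schema validation, deterministic OWL
    serialization to Turtle and RDF/XML, a SPARQL SELECT query layer with
    canned phenotype-decomposition and spatial-containment queries,
    segmentation-mask-linked quantitative histomorphometry (area,
    circularity, eccentricity, image entropy and the stromal
    tumor-infiltrating-lymphocyte fraction), and synthetic fixture
    generators that emit paired image/label-mask/document bundles with
    exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
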
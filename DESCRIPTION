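Package: osteoerode
Title: Micro-CT Bone Surface Erosion and Cortical Pore Quantification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies inflammation-driven bone surface erosion and cortical
    porosity on reconstructed micro-CT volumes of small skeletal elements such
    as murine tarsal and metatarsal bones. The bone mask is pore-filled by
    Euclidean-ball morphological closing composed with topological hole
    filling; the filled-minus-original difference, restricted to a stated
    distance from the bone surface, yields an erosion percentage, while the
    unrestricted difference quantifies fully enclosed cortical pores. Reports
    can be split per labeled bone and normalized against wild-type baseline
    scans. Includes a seeded synthetic bone-phantom generator with exact
    carved ground truth for validation, NRRD and MHD/RAW volume input/output,
    Otsu or fixed-value segmentation, and closed-form scoring of IgG Fc
    N-glycan profiles (relative sialylation, undergalactosylation score) and
    transwell chemotaxis migration indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
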
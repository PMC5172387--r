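Package: shapeherit
Title: Heritability Mapping of Vertex-Wise Subcortical Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates genetic contributions to vertex-wise subcortical brain
    shape from corresponded surface meshes. Extracts two shape descriptors per
    vertex (radial distance to a medial curve, log of the surface Jacobian
    determinant) and gross structure volume; builds a genomic relationship
    matrix (GRM) from dosage data with variant QC and relatedness pruning;
    estimates narrow-sense heritability per vertex by single-GRM restricted
    maximum likelihood with a Haseman-Elston fast path, and twin-based
    heritability by ACE maximum likelihood with a boundary mixture chi-squared
    likelihood-ratio test; maps test-retest reliability (ICC), reduces
    vertex-wise measures by PCA, and localizes significant heritability with
    Benjamini-Hochberg FDR control. Ships a synthetic-cohort generator with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
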
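Package: fibreimc
Title: Single-Fibre Analysis of Imaging Mass Cytometry from Skeletal Muscle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation and single-fibre statistical analysis of imaging
    mass cytometry (IMC) pseudo-images of transverse skeletal muscle
    sections. Fibres are segmented from a membrane channel (dystrophin),
    filtered by morphology, and quantified per channel. Oxidative
    phosphorylation deficiency is classified relative to mitochondrial mass
    (VDAC1) with two complementary methods: an ordinary-least-squares
    control regression with predictive intervals, and a kernel-density
    likelihood classifier on theta, the angle a fibre makes with the origin
    in a target-versus-VDAC1 scatterplot. Spatial clustering of deficient
    fibres is tested with a hypergeometric neighbourhood-enrichment test.
    A synthetic mosaic generator produces pseudo-image stacks and
    ground-truth fibre tables with the statistical structure the analysis
    assumes, so the whole pipeline can be exercised without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
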
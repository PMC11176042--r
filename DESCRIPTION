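Package: glandmorph
Title: 3D Morphometry of Uterine Glands and Embryo Implantation Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of branched uterine glands and embryo
    implantation geometry from multi-channel 3D fluorescence volumes.
    Segments tubular glands from a gland-marker channel (rolling-ball style
    background subtraction, thresholding, 3D hole filling, lumen separation),
    skeletonizes each gland by topology-preserving 3D thinning, counts
    skeleton branch points and measures gland length, computes the
    embryo-uterine axis alignment angle from inner-cell-mass and
    abembryonic-pole points against the mesometrial-antimesometrial axis,
    quantifies transcript signal volume per compartment volume, and applies
    the matching nonparametric statistics (Mann-Whitney, Kruskal-Wallis with
    Dunn's pairwise comparisons, two-proportion Z-test). A synthetic scene
    generator renders ground-truth luminal tubes, gland trees, blastocysts
    and punctate signal into noisy confocal-like z-stacks so that every
    pipeline stage is verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    yaml,
    EBImage,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
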
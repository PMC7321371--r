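Package: swarmfold
Title: Template-Based Protein Structure Prediction in Regularized LDA Reduced Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Template-based prediction of protein C-alpha backbone structure
    from an ensemble of decoy templates. Templates are filtered by an energy
    percentile cutoff, partitioned by one-dimensional k-means on energy, and
    embedded in a low-dimensional search space built from an L2-regularized
    linear discriminant analysis of the coordinate ensemble plus a
    high-frequency residual term. The reduced coordinates are sampled with a
    bounded particle swarm optimizer with dispersion-based collapse detection,
    and the resulting model is refined by optimizing the three singular-value
    coordinates of its coordinate matrix. Includes a synthetic decoy-ensemble
    generator with planted class structure so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
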
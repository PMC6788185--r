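Package: compostmap
Title: Compost Maturity Classification from Image Colour Statistics with
    Self-Organising Maps and LVQ1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the maturity of composted organic matter from digital
    images of its surface. Thirty colour-statistic descriptors (mean, median
    and standard deviation of HSV saturation, BT.601 luminance and the red,
    green and blue channels, computed over all pixels and over non-black
    pixels) feed a 15x15 Kohonen self-organising feature map trained without
    supervision, whose nodes are labelled by majority vote into five maturity
    classes and fine-tuned with the supervised LVQ1 rule. Includes a synthetic
    benchmark generator emulating class-conditional compost colour
    distributions, a stratified 2:1:1 train/validation/test splitter,
    classification-quality and root-mean-square-error evaluation, model
    serialisation, ggplot2 visualisations and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
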
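Package: rhizonet
Title: Condition-Specific Microbial Co-Occurrence Networks from Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers condition-specific rhizosphere co-occurrence networks from
    OTU count tables using a sparse Poisson log-normal latent Gaussian model
    with per-sample sequencing-depth offsets, a graphical-lasso penalty path,
    and StARS stability selection. Networks from different cropping conditions
    (bare soil, sole crops, intercrops) are then combined by signed edge
    arithmetic: intercrop networks are cleaned of bare-soil and sole-crop
    edges and intersected into unique and common fractions. Supporting tools
    cover count-table preprocessing (cross-experiment pooling, prevalence
    filtering, rarefaction), alpha diversity, unweighted UniFrac, PCoA,
    strata-restricted PERMANOVA, network summary metrics (degree, betweenness,
    sign ratios, modules, keystone taxa), and a synthetic-data generator with
    known ground-truth networks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    vegan,
    permute,
    picante,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
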
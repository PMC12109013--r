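Package: ki67gan
Title: Ki67-Conditioned Generation and Evaluation of Synthetic HE Histology Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the Ki67 proliferation index is expressed
    in Hematoxylin and Eosin (HE) stained histology image patches with a
    conditional style-based generative adversarial network. Provides a
    synthetic HE/Ki67 patch-pair simulator with known ground-truth indices, a
    semi-automated Ki67 annotation pipeline (colour clustering, brown-pixel
    quantification, patch quality filtering), a compact Ki67-conditioned
    style-mapping GAN trainable on a single CPU, Frechet-distance metrics
    (FID and the histological FHD variant) and perceptual path length against
    a pluggable embedder contract, a Ki67-interval evaluation protocol with
    subset/complement expectation checks, Ki67-sweep sequence generation, and
    ordinal inter-rater consistency analysis of pathologist verdicts.
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
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
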
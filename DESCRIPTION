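Package: dgmeval
Title: Evaluation of Deep Generative Models of Anthropomorphic Breast Phantom Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for assessing how well deep generative models reproduce
    the image statistics of procedurally generated anthropomorphic breast
    phantom slices. Provides a synthetic slice generator with known tissue
    layouts and prescribed per-tissue intensity laws, threshold-based tissue
    segmentation, a large registry of interpretable image features (gray-level
    co-occurrence texture, morphology, ligament skeleton statistics, fractal
    box dimension and lacunarity, image moments and Hu invariants), a
    two-stage evaluation pipeline (memorization screening and Frechet
    distance, then a bootstrapped Kolmogorov-Smirnov ranking metric on cosine
    distances in feature principal-component space), and diagnostic analyses
    of class prevalence, density and coverage, ensemble-mean semivariance,
    and common generation artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
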
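Package: readrsa
Title: Representational Similarity Analysis of Aloud and Silent Word Reading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A searchlight representational similarity analysis (RSA) pipeline
    for single-word reading fMRI experiments contrasting aloud and silent
    reading. Builds five word-pair hypothesis dissimilarity models (visual
    silhouette, open-bigram orthographic, MFCC-based acoustic-phonological,
    embedding-based semantic, and feature-weighted articulatory edit distance)
    and screens them for mutual independence with correlation Bayes factors;
    estimates single-trial activation patterns with least-squares-all (LSA)
    GLMs under a gamma haemodynamic response model; regresses searchlight
    neural dissimilarity matrices on the five models to obtain whole-volume
    beta maps; and performs group inference with voxelwise JZS Bayes-factor
    t-tests, evidence thresholding, directional contrast masking, and
    connected-component cluster reporting. Includes a synthetic-study
    generator that plants known representational geometry into simulated
    BOLD data so the whole pipeline can be exercised and validated without
    any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
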
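Package: ssrsa
Title: Spatiotemporal Searchlight Representational Similarity Analysis with
    Dynamic Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bidirectional representational comparison between artificial
    speech-recognition networks and source-space electrophysiology. Builds
    dynamic representational dissimilarity matrix (RDM) streams from layer
    activation timelines (frame reservation, delta features, context
    stacking), computes spatiotemporal searchlight RDMs on a cortical mesh,
    matches model to brain RDM streams at systematic processing latencies
    with Spearman rank correlation, performs group inference with
    threshold-free cluster enhancement (TFCE) and map-maximum sign-flip
    randomization, and evaluates phonetic/featural clustering of layer
    representational spaces with Davies-Bouldin indices, permutation nulls
    and Sammon mapping. Includes a synthetic-data generator with planted
    effects so the full pipeline is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    MASS,
    stats,
    utils,
    tools,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
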
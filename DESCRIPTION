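Package: dnapreview
Title: Tiered File Preview Encoding, Access Simulation and Decoding for
    DNA Data Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a File Preview architecture for PCR-addressed DNA data
    storage: thermodynamically tiered primer and address design based on
    nearest-neighbor duplex free energies, progressive-JPEG partitioning into
    Hamming-distance tiers, two-level Reed-Solomon protection with a
    GC-balanced comma-free codebook, simulation of stringent versus
    promiscuous PCR access over a strand library with competitive primer
    partitioning and error-prone background generation, seeded Levenshtein
    message-passing clustering of noisy sequencing reads, and the storage
    density and sequencing cost economics of Preview encoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
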
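Package: ecorisknet
Title: Soil Microbial Community Responses to Graded Heavy-Metal Ecological Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for soil microcosm studies that
    expose microbial communities to graded heavy-metal ecological risk.
    Implements the Hakanson potential ecological risk index (RI) with inverse
    design of metal additions to hit target RI levels; alpha diversity (ACE,
    Shannon, Faith PD), abundant/rare taxon partitioning, Bray-Curtis
    ordination and PERMANOVA; Biolog ECO/FF community-level physiological
    profiling (AWCD, substrate-group intensities, functional diversity);
    high-throughput qPCR functional-gene quantification with efficiency and
    detection-limit rules; random-matrix-theory thresholded co-occurrence
    networks with topology, Zi-Pi keystone roles, robustness and vulnerability;
    Sloan neutral community model fitting and the modified stochasticity ratio
    (MST); and seeded synthetic-data generators that emulate the full study
    design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
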
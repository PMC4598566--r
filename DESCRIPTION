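Package: ciliadyn
Title: Quantification of Cilia Dynamics, Basal-Body Polarity and Ciliary Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify primary-cilium assembly and disassembly from
    two-channel 3D fluorescence stacks (centrosome marker plus acetylated
    alpha-tubulin axoneme marker), rotational and translational basal-body
    polarity in multiciliated epithelia via circular statistics, cilia-driven
    bead-flow velocity and tortuosity from particle trajectories, and LUMIER
    interaction-screen hit calling. Includes synthetic-data generators that
    emulate each input modality with known ground truth, so every stage of
    the pipeline can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
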
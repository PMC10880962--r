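Package: jawgrowth
Title: Mechanoregulated Anisotropic Growth of the Larval Zebrafish Jaw Joint
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies local tissue growth tensors from tracked chondrocyte
    centroids (the statistical symmetrised velocity gradient on cubic regions
    of interest), simulates larval zebrafish jaw motion with a linear-elastic
    tetrahedral finite-element model to extract hydrostatic stress fields and
    their spatial gradients, combines an immobilised baseline growth map with
    candidate mechanobiological stimuli (cycle-averaged stress, stress
    gradients, compressive stress gradients), and simulates joint
    morphogenesis to compare predicted shapes against the free-to-move
    outcome. Ships a synthetic rudiment generator (parametric Meckel's
    cartilage / palatoquadrate / ceratohyal / interzone assembly with
    calibrated ground-truth deformation fields) so the whole pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
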
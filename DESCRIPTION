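Package: slamr
Title: Spatio-Linear Alignment of Macromolecules for Binding-Site Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects local three-dimensional similarity between protein
    ligand-binding cavities and solvent-exposed surface patches. Each heavy
    atom's neighborhood is encoded as a distance-sorted linear sequence of
    physicochemically annotated atoms (hydrogen-bond donor/acceptor,
    bulkiness, electropositivity, reduced amino-acid alphabet), sequences are
    aligned all-against-all with an affine-gap Needleman-Wunsch algorithm,
    recurrent atom matches are consolidated by correlation-constrained
    agglomerative clustering into one-to-one 3D alignments scored by
    Ncorr5 = N * r^5, and ligand poses are transferred by Kabsch superposition
    and assessed with a free-energy score. Includes ligand-cavity and
    surface-patch extraction (Shrake-Rupley solvent-accessible surface area),
    Gumbel extreme-value score calibration, screen evaluation (ROC/AUC), and
    deterministic synthetic structure generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    Biostrings,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
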
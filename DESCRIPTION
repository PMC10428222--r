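Package: coagdesign
Title: Trajectory Interaction Analysis and Rational Design of Dual-Agonist
    Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing peptide-receptor complexes from molecular
    dynamics style trajectories and for rationally designing dual-agonist
    (coagonist) peptides against the glucagon and GLP-1 receptors. Provides
    trajectory interaction metrics (fraction of native contacts, RMSD, RMSF,
    radius of gyration, hydrogen-bond occupancy networks, salt bridges,
    domain-wise interaction maps), an end-point MM-GB/SA style binding free
    energy with per-residue decomposition and variant difference maps, a
    mutation-selection and chimera-grafting design engine, two-dimensional
    free-energy surfaces over order-parameter pairs, and a synthetic
    complex/trajectory generator with planted, quantitatively known
    interaction structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
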
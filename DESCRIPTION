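Package: pocketcons
Title: Ligand-Binding Site Prediction from Probe Interaction Energies and
    Residue Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-ligand binding sites by placing carbon-atom
    probes on a regular grid around a protein structure, scoring each probe
    with a Lennard-Jones 6-12 van der Waals energy under the AMBER parm94
    nonbonded parameters, growing candidate pockets with an incremental
    energy-threshold clustering procedure, and re-ranking the resulting
    clusters with a weighted score that combines probe energy with
    per-residue sequence conservation (Jensen-Shannon divergence of
    PSI-BLAST PSSM or alignment-derived amino-acid frequencies against a
    background distribution). Includes ligand selection filters, binding-space
    precision and binding-residue S_residue/MCC evaluation protocols, a
    synthetic pocket fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
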
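Package: p31shift
Title: Conformer-Ensemble Prediction and Evaluation of 31P NMR Chemical Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting phosphorus-31 NMR chemical shifts from
    conformer ensembles and for evaluating predictions against experiment.
    Implements energy-window conformer selection, greedy RMSD-based ensemble
    pruning with optimal Kabsch superposition, Boltzmann-weighted averaging of
    isotropic shieldings, referencing of shieldings to the trimethylphosphine
    scale, and stratified error analysis (by solvent, molecule size, rotatable
    bonds and organophosphorus compound class). A deterministic synthetic-data
    generator and shielding surrogate stand in for quantum-chemical backends so
    the full pipeline is testable without electronic-structure calculations.
    Molecule tables are plain data frames; readers and writers cover CSV
    molecule tables, multi-conformer XYZ files and SDF files with
    NMReData-style shift tags.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
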
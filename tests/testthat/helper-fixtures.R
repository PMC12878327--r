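# Fixture builders: everything is generated in code, nothing read from
# disk except through tempfiles the tests write themselves.

make_ensemble <- function(coords, delta_G, mol_id = "M1", sigma_P = NULL, ...) {
  conformer_ensemble(
    mol_id = mol_id, coords = coords, delta_G = delta_G,
    sigma_P = sigma_P, ...
  )
}

# Random ensemble with cluster structure: conformers scatter around a few
# distinct centres, so some pairs are near-duplicates (sub-threshold RMSD)
# and others are well separated.
random_clustered_ensemble <- function(n_conf, n_atoms = 6, n_centres = 3,
                                      mol_id = "R1") {
  centres <- lapply(seq_len(n_centres), function(i) matrix(stats::runif(n_atoms * 3, -4, 4), ncol = 3))
  coords <- lapply(seq_len(n_conf), function(k) {
    centres[[sample.int(n_centres, 1)]] + matrix(stats::rnorm(n_atoms * 3, sd = 0.08), ncol = 3)
  })
  make_ensemble(coords, delta_G = stats::runif(n_conf, 0, 6), mol_id = mol_id)
}

write_molecule_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path, progress = FALSE)
  path
}

zero_offsets <- list(
  solvent_offsets = c(CHCl3 = 0, DMSO = 0, toluene = 0, H2O = 0, CH3CN = 0),
  class_offsets = c(
    monoalkyl_phosphinate = 0, phosphonite = 0, phosphonate = 0,
    dialkyl_phosphinate = 0, other = 0
  )
)

quiet_pipeline <- function(config) {
  suppressMessages(suppressWarnings(run_pipeline(config)))
}
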
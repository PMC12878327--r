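# Synthetic organophosphorus data sets. The generator emulates the
# statistical structure the evaluation assumes -- a grammar of alkyl
# scaffolds covering the four phosphorus ester classes plus "other",
# conformer counts growing steeply with molecule size, exponential-like
# relative Gibbs energies inside the thermal window, mostly-unknown solvent
# metadata dominated by chloroform, and solvent-/class-dependent systematic
# offsets plus Gaussian noise between "experiment" and the surrogate
# backend. It makes no attempt to mimic quantum-chemical shielding physics.

#' Configuration for the synthetic data generator
#'
#' Defaults state the emulated world once: solvent assignment frequencies
#' and the known-solvent fraction follow the cohort sizes of large
#' phosphorus-31 shift collections (chloroform dominating a known subset of
#' about a third of the records); per-class true-shift means follow the
#' per-class experimental means of such collections; the conformer-count
#' law grows as a power of atom count, scaled so the mean generated
#' ensemble is around 15 conformers; energies follow a truncated
#' exponential inside the 6 kcal/mol window.
#'
#' @param n_molecules Number of molecules to generate.
#' @param seed Master seed; every molecule derives its own stream from it.
#' @param noise_sd SD (ppm) of the Gaussian error between the surrogate
#'   "truth" and the synthetic experimental shift.
#' @param solvent_offsets Named ppm offsets added to the experimental shift
#'   per assigned solvent (systematic solvent effect).
#' @param class_offsets Named ppm offsets per compound class (systematic
#'   class effect, never removed by any modelled condition).
#' @param solvent_known_fraction Probability that a record's assigned
#'   solvent is revealed rather than reported as `"unknown"`.
#' @param solvent_freqs Sampling weights of the assigned solvents.
#' @param conformer_law `c(a, b, scale, max)`: the mean conformer count is
#'   `scale * a * n_atoms^b`, capped at `max` and at least 1.
#' @param energy_scale Mean (kcal/mol) of the exponential relative-Gibbs
#'   energy law before truncation to `energy_window`.
#' @param energy_window Truncation window for generated energies, kcal/mol.
#' @param geometry_jitter Per-atom Gaussian jitter SD (Angstrom) applied to
#'   each conformer around the molecule's base geometry.
#' @param g_amplitude Amplitude (ppm) of the deterministic per-conformer
#'   shielding perturbation applied by the surrogate backend.
#' @param sigma_ref Surrogate shielding of trimethylphosphine (ppm).
#' @param temperature Ensemble temperature in K.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_molecules = 100L,
                             seed = 1L,
                             noise_sd = 5,
                             solvent_offsets = c(
                               CHCl3 = 3, DMSO = -2, toluene = 4,
                               H2O = -5, CH3CN = 2
                             ),
                             class_offsets = c(
                               monoalkyl_phosphinate = 3, phosphonite = -8,
                               phosphonate = 2, dialkyl_phosphinate = -4,
                               other = 0
                             ),
                             solvent_known_fraction = 0.32,
                             solvent_freqs = c(
                               CHCl3 = 2955, DMSO = 43, toluene = 11,
                               H2O = 205, CH3CN = 4
                             ),
                             conformer_law = c(a = 0.0314, b = 2.515, scale = 0.1, max = 30),
                             energy_scale = 2.0,
                             energy_window = 6.0,
                             geometry_jitter = 0.4,
                             g_amplitude = 2.0,
                             sigma_ref = 350,
                             temperature = 298.15) {
  if (!is.numeric(n_molecules) || n_molecules < 1) {
    abort("`n_molecules` must be >= 1.")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (solvent_known_fraction < 0 || solvent_known_fraction > 1) {
    abort("`solvent_known_fraction` must be in [0, 1].")
  }
  structure(
    list(
      n_molecules = as.integer(n_molecules),
      seed = as.integer(seed),
      noise_sd = noise_sd,
      solvent_offsets = solvent_offsets,
      class_offsets = class_offsets,
      solvent_known_fraction = solvent_known_fraction,
      solvent_freqs = solvent_freqs,
      conformer_law = conformer_law,
      energy_scale = energy_scale,
      energy_window = energy_window,
      geometry_jitter = geometry_jitter,
      g_amplitude = g_amplitude,
      sigma_ref = sigma_ref,
      temperature = temperature
    ),
    class = "synthetic_config"
  )
}

# Scaffold grammar: alkyl chains on the four ester-class cores plus
# phosphines/phosphites/phosphine oxides as "other". Chain lengths >= 2 so
# the phosphorus-bound carbon is a true RCH2 group. True-shift class means
# follow typical experimental per-class means; "other" subtypes get
# literature-typical centres.
SYN_CLASS_PROBS <- c(
  monoalkyl_phosphinate = 0.10, phosphonite = 0.10,
  phosphonate = 0.18, dialkyl_phosphinate = 0.18, other = 0.44
)

SYN_CLASS_MEANS <- c(
  monoalkyl_phosphinate = 24.7, phosphonite = 115.2,
  phosphonate = 18.3, dialkyl_phosphinate = 34.3
)

SYN_OTHER_SUBTYPES <- c(phosphine = -40, phosphite = 135, phosphine_oxide = 40)

syn_smiles <- function(class_label, subtype, chains) {
  alk <- function(n) strrep("C", n)
  r1 <- alk(chains[1])
  r2 <- alk(chains[2])
  r3 <- alk(chains[3])
  switch(class_label,
    monoalkyl_phosphinate = sprintf("%s[PH](=O)O%s", r1, r2),
    phosphonite = sprintf("%sP(O%s)O%s", r1, r2, r3),
    phosphonate = sprintf("%sP(=O)(O%s)O%s", r1, r2, r3),
    dialkyl_phosphinate = sprintf("%sP(=O)(%s)O%s", r1, r2, r3),
    other = switch(subtype,
      phosphine = sprintf("%sP(%s)%s", r1, r2, r3),
      phosphite = sprintf("%sOP(O%s)O%s", r1, r2, r3),
      phosphine_oxide = sprintf("%sP(=O)(%s)%s", r1, r2, r3)
    )
  )
}

# Base 3D geometry for a synthetic molecule: a random walk with 1.5 A
# steps over all atoms (hydrogens included). Not a physical geometry; it
# only has to give conformer RMSDs on the Angstrom scale.
syn_base_geometry <- function(n_atoms) {
  steps <- matrix(stats::rnorm(n_atoms * 3), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * 1.5
  apply(steps, 2, cumsum)
}

syn_elements <- function(smiles) {
  g <- parse_smiles(smiles)
  c(g$atoms$element, rep("H", sum(g$atoms$n_h)))
}

#' Generate a synthetic data set for the full pipeline
#'
#' Draws molecules from the scaffold grammar, assigns each a latent true
#' shift, a solvent (revealed with probability
#' `solvent_known_fraction`), a conformer ensemble with truncated
#' exponential relative Gibbs energies and jittered geometries, and a
#' noisy experimental shift
#' `delta_exp = delta_true + solvent_offset + class_offset + N(0, noise_sd)`.
#' All randomness derives from `config$seed` through one counter-based
#' stream per molecule, so runs are reproducible and any subset of
#' molecules is independent of the others.
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (molecule table), `ensembles` (named list
#'   of [conformer_ensemble()]), `ground_truth` (tibble of every latent
#'   value) and `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  classes <- names(SYN_CLASS_PROBS)
  law <- config$conformer_law

  one_molecule <- function(i) {
    with_local_seed(derive_seed(config$seed, i), {
      class_label <- if (i <= length(classes)) {
        classes[i] # first molecules cycle the grammar: every class present
      } else {
        sample(classes, 1, prob = SYN_CLASS_PROBS)
      }
      subtype <- if (class_label == "other") {
        sample(names(SYN_OTHER_SUBTYPES), 1)
      } else {
        NA_character_
      }
      chains <- sample(2:8, 3, replace = TRUE)
      smiles <- syn_smiles(class_label, subtype, chains)
      centre <- if (class_label == "other") {
        SYN_OTHER_SUBTYPES[[subtype]]
      } else {
        SYN_CLASS_MEANS[[class_label]]
      }
      delta_true <- centre + stats::rnorm(1, sd = 15)
      solvent_assigned <- sample(
        names(config$solvent_freqs), 1,
        prob = config$solvent_freqs
      )
      solvent_known <- stats::runif(1) < config$solvent_known_fraction
      noise <- stats::rnorm(1, sd = config$noise_sd)

      elements <- syn_elements(smiles)
      n_atoms <- length(elements)
      mean_conf <- law[["scale"]] * law[["a"]] * n_atoms^law[["b"]]
      n_conf <- max(1L, min(as.integer(law[["max"]]), stats::rpois(1, mean_conf)))
      rate <- 1 / config$energy_scale
      dg <- if (n_conf > 1) {
        sort(c(0, stats::qexp(
          stats::runif(n_conf - 1) * stats::pexp(config$energy_window, rate),
          rate
        )))
      } else {
        0
      }
      base <- syn_base_geometry(n_atoms)
      coords <- lapply(seq_len(n_conf), function(k) {
        base + matrix(stats::rnorm(n_atoms * 3, sd = config$geometry_jitter), ncol = 3)
      })
      mol_id <- sprintf("SYN%05d", i)
      solvent_offset <- lookup_or_zero(config$solvent_offsets, solvent_assigned)
      class_offset <- lookup_or_zero(config$class_offsets, class_label)
      list(
        record = tibble(
          mol_id = mol_id,
          smiles = smiles,
          delta_exp = delta_true + solvent_offset + class_offset + noise,
          solvent = if (solvent_known) solvent_assigned else "unknown"
        ),
        truth = tibble(
          mol_id = mol_id,
          class_label = class_label,
          subtype = subtype,
          delta_true = delta_true,
          solvent_assigned = solvent_assigned,
          solvent_known = solvent_known,
          solvent_offset = solvent_offset,
          class_offset = class_offset,
          noise = noise,
          n_atoms = n_atoms,
          n_conformers = n_conf
        ),
        ensemble = conformer_ensemble(
          mol_id = mol_id, coords = coords, delta_G = dg,
          elements = elements, temperature = config$temperature
        )
      )
    })
  }

  mols <- purrr::map(seq_len(config$n_molecules), one_molecule)
  records <- suppressMessages(
    as_molecule_table(dplyr::bind_rows(purrr::map(mols, "record")))
  )
  ensembles <- purrr::map(mols, "ensemble")
  names(ensembles) <- records$mol_id
  list(
    records = records,
    ensembles = ensembles,
    ground_truth = dplyr::bind_rows(purrr::map(mols, "truth")),
    config = config
  )
}

#' Surrogate per-conformer shieldings
#'
#' The deterministic stand-in for a quantum-chemical shielding backend.
#' For conformer `i` of a molecule with latent true shift `delta_true`:
#' `sigma_i = sigma_ref - (delta_true - delta_ref_exp) + g_i + s`, where
#' `g_i` is a bounded perturbation keyed on the conformer geometry (so it
#' survives pruning and reordering) and `s` cancels the molecule's solvent
#' offset when `condition` names its assigned solvent -- modelling the
#' right solvent removes that solvent's systematic bias, vacuum or a wrong
#' solvent leaves it in place. Converting these shieldings back through
#' the physical referencing scheme recovers `delta_true` exactly when
#' `g_amplitude` is 0 and the condition is `"vac"` with zero offsets.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param condition `"vac"` or a canonical solvent label.
#' @param ground_truth The `ground_truth` tibble from [generate_dataset()].
#' @param sigma_ref Surrogate PMe3 shielding (ppm).
#' @param g_amplitude Bound (ppm) on the conformer perturbation.
#' @param delta_ref_exp Experimental PMe3 shift (ppm).
#' @return Numeric vector of shieldings, one per conformer.
#' @export
surrogate_shielding <- function(ensemble, condition, ground_truth,
                                sigma_ref = 350, g_amplitude = 2,
                                delta_ref_exp = -62.0) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  row <- ground_truth[ground_truth$mol_id == ensemble$mol_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort(sprintf("Molecule %s is not in the ground truth.", ensemble$mol_id))
  }
  s <- if (condition == row$solvent_assigned) -row$solvent_offset else 0
  g <- vapply(
    ensemble$conformers$coords,
    function(xyz) g_amplitude * hash_unit(xyz),
    double(1)
  )
  sigma_ref - (row$delta_true - delta_ref_exp) + g + s
}

#' Shielding backends
#'
#' A backend maps a conformer ensemble and a condition label to
#' per-conformer isotropic phosphorus shieldings, and carries the
#' reference shielding `sigma_ref` of trimethylphosphine computed under
#' its own settings. `surrogate_backend()` wraps [surrogate_shielding()]
#' over a synthetic ground truth; `precomputed_backend()` serves
#' shieldings from a table (columns `mol_id`, `conf_id`, `condition`,
#' `sigma_ppm`), e.g. parsed from real quantum-chemistry output.
#'
#' @param ground_truth Ground-truth tibble from [generate_dataset()].
#' @param sigma_ref Reference (PMe3) shielding in ppm.
#' @param g_amplitude Conformer perturbation bound in ppm.
#' @param delta_ref_exp Experimental PMe3 shift in ppm.
#' @return A list of class `p31_backend` with elements `shielding`
#'   (`function(ensemble, condition)`), `sigma_ref` and `label`.
#' @export
surrogate_backend <- function(ground_truth, sigma_ref = 350, g_amplitude = 2,
                              delta_ref_exp = -62.0) {
  structure(
    list(
      shielding = function(ensemble, condition) {
        surrogate_shielding(
          ensemble, condition, ground_truth,
          sigma_ref = sigma_ref, g_amplitude = g_amplitude,
          delta_ref_exp = delta_ref_exp
        )
      },
      sigma_ref = sigma_ref,
      label = "surrogate"
    ),
    class = "p31_backend"
  )
}

#' @rdname surrogate_backend
#' @param shieldings Data frame (or CSV path) with columns `mol_id`,
#'   `conf_id`, `condition`, `sigma_ppm`.
#' @export
precomputed_backend <- function(shieldings, sigma_ref) {
  if (is.character(shieldings) && length(shieldings) == 1L) {
    shieldings <- readr::read_csv(
      shieldings,
      col_types = "cccd", progress = FALSE, show_col_types = FALSE
    )
  }
  shieldings <- as_tibble(shieldings)
  need <- c("mol_id", "conf_id", "condition", "sigma_ppm")
  if (!all(need %in% names(shieldings))) {
    abort("Precomputed shieldings need columns mol_id, conf_id, condition, sigma_ppm.")
  }
  stopifnot_scalar_number(sigma_ref, "sigma_ref")
  structure(
    list(
      shielding = function(ensemble, condition) {
        sub <- shieldings[
          shieldings$mol_id == ensemble$mol_id &
            shieldings$condition == condition, ,
          drop = FALSE
        ]
        idx <- match(ensemble$conformers$conf_id, sub$conf_id)
        if (anyNA(idx)) {
          abort(sprintf(
            "No precomputed shielding for %s conformer(s) %s under condition '%s'.",
            ensemble$mol_id,
            paste(ensemble$conformers$conf_id[is.na(idx)], collapse = ", "),
            condition
          ))
        }
        sub$sigma_ppm[idx]
      },
      sigma_ref = sigma_ref,
      label = "precomputed"
    ),
    class = "p31_backend"
  )
}
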
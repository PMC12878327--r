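#' Pipeline configuration
#'
#' Describes one end-to-end run: where molecules and ensembles come from
#' (a synthetic configuration, or a molecule CSV plus a directory of
#' multi-conformer XYZ files), which shielding backend to use, the
#' referencing scheme, pruning parameters, the conditions to compute and
#' where to write outputs.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading files.
#' @param molecule_csv,ensemble_dir File inputs: a molecule table CSV and a
#'   directory holding one `<mol_id>.xyz` per molecule. Ignored when
#'   `synthetic` is given; exactly one input source must be configured.
#' @param backend `"surrogate"` (synthetic input only), a `p31_backend`,
#'   or a path/data frame of precomputed shieldings for
#'   [precomputed_backend()] (then `sigma_ref` must be given).
#' @param sigma_ref Reference shielding when `backend` is precomputed.
#' @param convention Referencing convention, see [reference_scheme()].
#' @param prune A [prune_config()].
#' @param conditions Conditions to compute: `"vac"` is always computed;
#'   `"matched"` adds, per molecule with known solvent, that solvent;
#'   canonical solvent names add that solvent for every molecule.
#' @param temperature Ensemble temperature in K.
#' @param shift_range Shift range (ppm) for relative MAE reporting.
#' @param output_dir Directory for written outputs, or `NULL` to skip
#'   writing.
#' @param verbose Log per-run progress (every 100 molecules).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL,
                            molecule_csv = NULL,
                            ensemble_dir = NULL,
                            backend = "surrogate",
                            sigma_ref = NULL,
                            convention = c("physical", "as_printed"),
                            prune = prune_config(),
                            conditions = c("vac", "matched"),
                            temperature = 298.15,
                            shift_range = 698,
                            output_dir = NULL,
                            verbose = FALSE) {
  convention <- match.arg(convention)
  from_files <- !is.null(molecule_csv) || !is.null(ensemble_dir)
  if (is.null(synthetic) && !from_files) {
    abort("Configure an input source: `synthetic`, or `molecule_csv` + `ensemble_dir`.")
  }
  if (!is.null(synthetic) && from_files) {
    abort("Configure exactly one input source, not both.")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    abort("`synthetic` must be a synthetic_config().")
  }
  if (from_files && (is.null(molecule_csv) || is.null(ensemble_dir))) {
    abort("File input needs both `molecule_csv` and `ensemble_dir`.")
  }
  if (from_files && identical(backend, "surrogate")) {
    abort("The surrogate backend needs synthetic input; use a precomputed backend for file input.")
  }
  bad <- setdiff(conditions, c("vac", "matched", CANONICAL_SOLVENTS))
  if (length(bad)) {
    abort(sprintf("Unknown condition label(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(conditions) == 0L) abort("`conditions` must be nonempty.")
  stopifnot(inherits(prune, "prune_config"))
  structure(
    list(
      synthetic = synthetic, molecule_csv = molecule_csv,
      ensemble_dir = ensemble_dir, backend = backend, sigma_ref = sigma_ref,
      convention = convention, prune = prune,
      conditions = unique(c("vac", conditions)),
      temperature = temperature, shift_range = shift_range,
      output_dir = output_dir, verbose = verbose
    ),
    class = "pipeline_config"
  )
}

#' Run the full prediction and evaluation pipeline
#'
#' Executes, for every molecule: energy-window filtering, RMSD-based
#' pruning, backend shieldings per condition, Boltzmann averaging and
#' referencing; then evaluates the predictions against experimental shifts
#' with [stratified_report()]. Failures are isolated per molecule: a bad
#' molecule is logged and skipped, never aborting the run. When
#' `output_dir` is set, writes `nmredata.sdf`, `predictions.csv`,
#' `report_metrics.csv`, `report_improvements.csv` and `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `p31_pipeline`: list with `records`,
#'   `predictions`, `shifts` (the evaluation series), `report`
#'   (a `p31_report`), `manifest` and `ground_truth` (synthetic input
#'   only).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$synthetic)) {
    data <- generate_dataset(config$synthetic)
    records <- data$records
    ensembles <- data$ensembles
    ground_truth <- data$ground_truth
    backend <- if (identical(config$backend, "surrogate")) {
      surrogate_backend(
        ground_truth,
        sigma_ref = config$synthetic$sigma_ref,
        g_amplitude = config$synthetic$g_amplitude
      )
    } else {
      resolve_backend(config)
    }
  } else {
    records <- read_molecule_table(config$molecule_csv)
    paths <- file.path(config$ensemble_dir, paste0(records$mol_id, ".xyz"))
    missing <- !file.exists(paths)
    if (all(missing)) {
      abort(sprintf("No ensemble XYZ files found under %s", config$ensemble_dir))
    }
    if (any(missing)) {
      warn(sprintf(
        "No ensemble file for %d molecule(s); they will be skipped.",
        sum(missing)
      ))
    }
    ensembles <- purrr::map2(
      paths[!missing], records$mol_id[!missing],
      function(p, id) read_conformer_xyz(p, mol_id = id, temperature = config$temperature)
    )
    names(ensembles) <- records$mol_id[!missing]
    ground_truth <- NULL
    backend <- resolve_backend(config)
  }

  scheme <- reference_scheme(
    sigma_ref = backend$sigma_ref,
    convention = config$convention
  )

  failures <- list()
  predictions <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    res <- tryCatch(
      {
        ens <- ensembles[[rec$mol_id]]
        if (is.null(ens)) abort("no conformer ensemble available")
        ens$temperature <- config$temperature
        ens <- filter_energy_window(ens, config$prune$energy_window)
        ens <- prune_ensemble(ens, config$prune)
        conds <- resolve_conditions(config$conditions, rec$solvent)
        dplyr::bind_rows(purrr::map(conds, function(cond) {
          ens$conformers$sigma_P <- backend$shielding(ens, cond)
          predict_molecule(rec$mol_id, ens, scheme, condition = cond)
        }))
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[rec$mol_id]] <- conditionMessage(res)
    } else {
      predictions[[i]] <- res
    }
    if (config$verbose && i %% 100 == 0) {
      inform(sprintf("processed %d / %d molecules", i, nrow(records)))
    }
  }
  predictions <- dplyr::bind_rows(predictions)
  n_ok <- length(unique(predictions$mol_id))
  if (n_ok == 0L) abort("All molecules failed; nothing to evaluate.")
  if (length(failures)) {
    warn(sprintf(
      "Skipped %d molecule(s): %s", length(failures),
      paste(names(failures), collapse = ", ")
    ))
  }

  shifts <- build_shift_series(predictions, records)
  report <- suppressMessages(stratified_report(
    records[records$mol_id %in% unique(predictions$mol_id), ],
    shifts,
    condition_pairs = list(
      c("vacuum_single", "vacuum_ensemble"),
      c("vacuum_single", "solvent_single")
    ),
    shift_range = config$shift_range
  ))

  manifest <- list(
    package_version = as.character(utils::packageVersion("p31shift")),
    seed = if (!is.null(config$synthetic)) config$synthetic$seed else NA,
    n_input = nrow(records),
    n_processed = n_ok,
    n_skipped = length(failures),
    failures = failures,
    conditions = config$conditions,
    convention = config$convention,
    temperature = config$temperature,
    prune = unclass(config$prune),
    sigma_ref = backend$sigma_ref,
    backend = backend$label
  )

  result <- structure(
    list(
      records = records, predictions = predictions, shifts = shifts,
      report = report, manifest = manifest, ground_truth = ground_truth
    ),
    class = "p31_pipeline"
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    write_molecule_table(records, out("molecules.csv"))
    write_nmredata_sdf(records, predictions, out("nmredata.sdf"))
    readr::write_csv(predictions, out("predictions.csv"), progress = FALSE)
    write_report_csv(report, out("report_metrics.csv"), out("report_improvements.csv"))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    result$files <- vapply(
      c(
        "molecules.csv", "nmredata.sdf", "predictions.csv",
        "report_metrics.csv", "report_improvements.csv", "manifest.json"
      ),
      out, character(1)
    )
  }
  result
}

resolve_backend <- function(config) {
  if (inherits(config$backend, "p31_backend")) {
    return(config$backend)
  }
  if (is.null(config$sigma_ref)) {
    abort("A precomputed backend needs `sigma_ref` (the PMe3 reference shielding).")
  }
  precomputed_backend(config$backend, sigma_ref = config$sigma_ref)
}

resolve_conditions <- function(conditions, solvent) {
  out <- setdiff(conditions, "matched")
  if ("matched" %in% conditions && solvent %in% CANONICAL_SOLVENTS) {
    out <- c(out, solvent)
  }
  unique(out)
}

#' Build the evaluation shift series from pipeline predictions
#'
#' Maps the per-condition prediction rows onto the four series the
#' stratified evaluation compares: `vacuum_single` (lowest-energy
#' conformer, vacuum), `vacuum_ensemble` (Boltzmann-weighted, vacuum) and
#' `solvent_single` / `solvent_ensemble` (the molecule's own solvent when a
#' prediction under it exists, falling back to the vacuum value so the
#' series stays complete for unknown-solvent records).
#'
#' @param predictions Predictions tibble (see [predict_molecule()]).
#' @param records The matching molecule table.
#' @return A long tibble: `mol_id`, `condition`, `delta_calc`.
#' @export
build_shift_series <- function(predictions, records) {
  vac <- predictions[predictions$condition == "vac", , drop = FALSE]
  solv <- dplyr::inner_join(
    predictions,
    records[, c("mol_id", "solvent")],
    by = "mol_id"
  )
  solv <- solv[solv$condition == solv$solvent, , drop = FALSE]
  matched <- dplyr::left_join(
    vac[, c("mol_id", "delta_single", "delta_boltzmann")],
    solv[, c("mol_id", "delta_single", "delta_boltzmann")],
    by = "mol_id", suffix = c("_vac", "_solv")
  )
  dplyr::bind_rows(
    tibble(
      mol_id = vac$mol_id, condition = "vacuum_single",
      delta_calc = vac$delta_single
    ),
    tibble(
      mol_id = vac$mol_id, condition = "vacuum_ensemble",
      delta_calc = vac$delta_boltzmann
    ),
    tibble(
      mol_id = matched$mol_id, condition = "solvent_single",
      delta_calc = dplyr::coalesce(matched$delta_single_solv, matched$delta_single_vac)
    ),
    tibble(
      mol_id = matched$mol_id, condition = "solvent_ensemble",
      delta_calc = dplyr::coalesce(matched$delta_boltzmann_solv, matched$delta_boltzmann_vac)
    )
  )
}

#' @export
print.p31_pipeline <- function(x, ...) {
  cat(sprintf(
    "<p31_pipeline> %d molecule(s) processed, %d skipped; conditions: %s\n",
    x$manifest$n_processed, x$manifest$n_skipped,
    paste(x$manifest$conditions, collapse = ", ")
  ))
  print(x$report)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `p31_pipeline`.
#' @param ... Unused.
#' @export
tidy.p31_pipeline <- function(x, ...) x$predictions

#' @rdname run_pipeline
#' @export
glance.p31_pipeline <- function(x, ...) {
  overall <- x$report$metrics
  overall <- overall[
    overall$cohort_kind == "all" & overall$condition == "vacuum_single", ,
    drop = FALSE
  ]
  tibble(
    n_input = x$manifest$n_input,
    n_processed = x$manifest$n_processed,
    n_skipped = x$manifest$n_skipped,
    rmse_vacuum_single = if (nrow(overall)) overall$rmse else NA_real_,
    sigma_ref = x$manifest$sigma_ref,
    convention = x$manifest$convention
  )
}
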
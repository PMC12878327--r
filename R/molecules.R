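CANONICAL_SOLVENTS <- c("CHCl3", "DMSO", "toluene", "H2O", "CH3CN")

P_CLASSES <- c(
  "monoalkyl_phosphinate", "phosphonite", "phosphonate",
  "dialkyl_phosphinate", "other"
)

#' Normalize a solvent label to its canonical name
#'
#' Labels are matched case-insensitively; deuterated spellings map to the
#' nondeuterated solvent (the dielectric continuum is the same medium), and
#' common trivial names are accepted. Anything unrecognized, empty or `NA`
#' becomes `"unknown"`.
#'
#' @param solvent Character vector of solvent labels.
#' @return Character vector over
#'   `c("CHCl3", "DMSO", "toluene", "H2O", "CH3CN", "unknown")`.
#' @examples
#' normalize_solvent(c("CDCl3", "dmso-d6", "Water", NA))
#' @export
normalize_solvent <- function(solvent) {
  lut <- c(
    "chcl3" = "CHCl3", "cdcl3" = "CHCl3", "chloroform" = "CHCl3",
    "chloroform-d" = "CHCl3",
    "dmso" = "DMSO", "dmso-d6" = "DMSO", "(cd3)2so" = "DMSO",
    "toluene" = "toluene", "toluene-d8" = "toluene", "c7h8" = "toluene",
    "h2o" = "H2O", "d2o" = "H2O", "water" = "H2O",
    "ch3cn" = "CH3CN", "cd3cn" = "CH3CN", "acetonitrile" = "CH3CN",
    "mecn" = "CH3CN",
    "unknown" = "unknown"
  )
  key <- tolower(trimws(as.character(solvent)))
  out <- unname(lut[key])
  out[is.na(out) | key == ""] <- "unknown"
  out
}

#' Coerce a data frame into a validated molecule table
#'
#' Ensures the columns required throughout the package are present and
#' consistent: `mol_id` (unique), `smiles` (parsable, at least one
#' phosphorus), `delta_exp` (ppm, may be `NA`), `solvent` (normalized via
#' [normalize_solvent()]), `n_atoms` and `n_rotatable_bonds` (computed from
#' the SMILES when absent) and `class_label` (via [classify_p_class()] when
#' absent). Rows whose SMILES fails to parse or contains no phosphorus are
#' dropped; the dropped rows are reported via a warning and attached as the
#' `"problems"` attribute.
#'
#' @param df A data frame with at least `mol_id` and `smiles` columns. A
#'   `delta_exp_ppm` column is accepted as an alias for `delta_exp`.
#' @return A tibble, one row per valid molecule, with attribute
#'   `"problems"` (tibble of `mol_id`, `row`, `message`).
#' @export
as_molecule_table <- function(df) {
  df <- as_tibble(df)
  if (!all(c("mol_id", "smiles") %in% names(df))) {
    abort("A molecule table needs at least `mol_id` and `smiles` columns.")
  }
  if ("delta_exp_ppm" %in% names(df) && !"delta_exp" %in% names(df)) {
    df <- dplyr::rename(df, delta_exp = "delta_exp_ppm")
  }
  df$mol_id <- as.character(df$mol_id)
  if (anyDuplicated(df$mol_id)) {
    abort(sprintf(
      "Duplicate mol_id in molecule table: %s",
      paste(unique(df$mol_id[duplicated(df$mol_id)]), collapse = ", ")
    ))
  }
  if (!"delta_exp" %in% names(df)) df$delta_exp <- NA_real_
  df$delta_exp <- as.double(df$delta_exp)
  df$solvent <- normalize_solvent(if ("solvent" %in% names(df)) df$solvent else NA)

  known <- c(
    "mol_id", "smiles", "delta_exp", "solvent",
    "n_atoms", "n_rotatable_bonds", "class_label"
  )
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    inform(sprintf(
      "Ignoring extra molecule-table column(s): %s",
      paste(extra, collapse = ", ")
    ))
  }

  parsed <- purrr::map(df$smiles, function(s) {
    tryCatch(
      {
        g <- parse_smiles(s)
        if (!any(g$atoms$element == "P")) {
          abort("molecule contains no phosphorus atom")
        }
        g
      },
      error = function(e) e
    )
  })
  bad <- purrr::map_lgl(parsed, inherits, "error")
  problems <- tibble(
    mol_id = df$mol_id[bad],
    row = which(bad),
    message = purrr::map_chr(parsed[bad], conditionMessage)
  )
  if (nrow(problems)) {
    warn(sprintf(
      "Dropped %d molecule(s) with invalid SMILES: %s",
      nrow(problems), paste(problems$mol_id, collapse = ", ")
    ))
  }
  out <- df[!bad, intersect(known, names(df))]
  kept <- parsed[!bad]
  if (!"n_atoms" %in% names(out) || anyNA(out$n_atoms)) {
    out$n_atoms <- purrr::map_int(kept, function(g) {
      as.integer(nrow(g$atoms) + sum(g$atoms$n_h))
    })
  }
  if (!"n_rotatable_bonds" %in% names(out) || anyNA(out$n_rotatable_bonds)) {
    out$n_rotatable_bonds <- purrr::map_int(out$smiles, smiles_rotatable_bonds)
  }
  if (!"class_label" %in% names(out) || anyNA(out$class_label)) {
    out$class_label <- purrr::map_chr(out$smiles, classify_p_class)
  }
  out <- out[, c(
    "mol_id", "smiles", "delta_exp", "solvent",
    "n_atoms", "n_rotatable_bonds", "class_label"
  )]
  attr(out, "problems") <- problems
  out
}

#' Read a molecule table from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row defining at least
#' `mol_id` and `smiles`; `delta_exp_ppm` and `solvent` are optional.
#' Rows with unparsable SMILES are skipped with a warning; duplicated
#' `mol_id` is an error. See [as_molecule_table()] for the derived columns.
#'
#' @param path Path to a CSV file.
#' @return A molecule-table tibble (see [as_molecule_table()]).
#' @export
read_molecule_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_guess(), mol_id = "c", smiles = "c"),
    progress = FALSE, show_col_types = FALSE
  )
  as_molecule_table(df)
}

#' Write a molecule table to CSV
#'
#' @param records A molecule-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(records, path) {
  out <- dplyr::rename(records, delta_exp_ppm = "delta_exp")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
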
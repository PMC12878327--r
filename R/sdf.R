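# NMReData-style SDF serialization. Shift predictions are carried in SDF
# data fields; the tag dialect is fixed here because the initiative's tag
# set has no slot for per-solvent computed shifts:
#   <NMREDATA_VERSION>, <SMILES>, <P31_SHIFT_VAC_PPM>,
#   <P31_SHIFT_BOLTZMANN_PPM>, <P31_SHIFT_CPCM_{CHCL3,DMSO,TOLUENE,H2O,CH3CN}_PPM>,
#   <P31_SHIFT_EXP_PPM>, <P31_SOLVENT_EXP>
# All ppm values are serialized with 2 decimals, the precision of the
# reported tables.

sdf_solvent_tag <- function(solvent) {
  sprintf("P31_SHIFT_CPCM_%s_PPM", toupper(solvent))
}

SDF_KNOWN_TAGS <- c(
  "NMREDATA_VERSION", "SMILES", "P31_SHIFT_VAC_PPM", "P31_SHIFT_BOLTZMANN_PPM",
  sdf_solvent_tag(CANONICAL_SOLVENTS), "P31_SHIFT_EXP_PPM", "P31_SOLVENT_EXP"
)

mol_block_from_smiles <- function(mol_id, smiles) {
  g <- parse_smiles(smiles)
  n_at <- nrow(g$atoms)
  n_bd <- nrow(g$bonds)
  c(
    mol_id, "  p31shift", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_at, n_bd),
    sprintf(
      "%10.4f%10.4f%10.4f %-2s  0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, g$atoms$element
    ),
    if (n_bd) {
      sprintf("%3d%3d%3d  0", g$bonds$from, g$bonds$to, as.integer(g$bonds$order))
    },
    "M  END"
  )
}

#' Write molecules and shift predictions as an NMReData-style SDF file
#'
#' Serializes one V2000 entry per molecule (connection table rebuilt from
#' the SMILES, coordinates zeroed) with shift data fields: the vacuum
#' single-point shift, the Boltzmann ensemble shift, one field per
#' implicit-solvent shift present, the experimental shift and the
#' experimental solvent. Fields whose value is absent are omitted.
#'
#' @param records A molecule table (see [as_molecule_table()]).
#' @param predictions A predictions tibble as returned by
#'   [predict_molecule()] / [run_pipeline()]: columns `mol_id`, `condition`
#'   (`"vac"` or a canonical solvent), `delta_single`, `delta_boltzmann`.
#'   Every `mol_id` in `predictions` must appear in `records`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nmredata_sdf <- function(records, predictions, path) {
  missing_ids <- setdiff(unique(predictions$mol_id), records$mol_id)
  if (length(missing_ids)) {
    abort(sprintf(
      "Predictions reference mol_id(s) absent from records: %s",
      paste(missing_ids, collapse = ", ")
    ))
  }
  fmt <- function(x) sprintf("%.2f", x)
  tag_lines <- function(tag, value) {
    if (is.null(value) || length(value) == 0L || is.na(value)) return(NULL)
    c(sprintf(">  <%s>", tag), as.character(value), "")
  }
  out <- character()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    pred <- predictions[predictions$mol_id == rec$mol_id, , drop = FALSE]
    vac <- pred[pred$condition == "vac", , drop = FALSE]
    entry <- c(
      mol_block_from_smiles(rec$mol_id, rec$smiles),
      tag_lines("NMREDATA_VERSION", "1.1"),
      tag_lines("SMILES", rec$smiles),
      if (nrow(vac)) tag_lines("P31_SHIFT_VAC_PPM", fmt(vac$delta_single[1])),
      if (nrow(vac)) tag_lines("P31_SHIFT_BOLTZMANN_PPM", fmt(vac$delta_boltzmann[1]))
    )
    for (sv in CANONICAL_SOLVENTS) {
      row <- pred[pred$condition == sv, , drop = FALSE]
      if (nrow(row)) {
        entry <- c(entry, tag_lines(sdf_solvent_tag(sv), fmt(row$delta_single[1])))
      }
    }
    entry <- c(
      entry,
      tag_lines("P31_SHIFT_EXP_PPM", if (is.na(rec$delta_exp)) NA else fmt(rec$delta_exp)),
      tag_lines("P31_SOLVENT_EXP", if (rec$solvent == "unknown") NA else rec$solvent),
      "$$$$"
    )
    out <- c(out, entry)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an NMReData-style SDF file written by [write_nmredata_sdf()]
#'
#' The inverse of [write_nmredata_sdf()] on its own output (shift values to
#' 2-decimal ppm). Data tags not in the dialect are preserved per molecule
#' in the `extra_tags` list-column. Entries with a malformed molecule block
#' are skipped with a warning.
#'
#' @param path Path to an SDF file.
#' @return A list with `records` (molecule table plus `extra_tags`
#'   list-column) and `predictions` (tibble of `mol_id`, `condition`,
#'   `delta_single`, `delta_boltzmann`).
#' @export
read_nmredata_sdf <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path)
  breaks <- which(trimws(lines) == "$$$$")
  starts <- c(1L, utils::head(breaks, -1) + 1L)
  rows <- list()
  preds <- list()
  extras <- list()
  skipped <- 0L
  for (e in seq_along(breaks)) {
    entry <- lines[starts[e]:(breaks[e] - 1L)]
    parsed <- tryCatch(parse_sdf_entry(entry), error = function(err) err)
    if (inherits(parsed, "error")) {
      skipped <- skipped + 1L
      next
    }
    tags <- parsed$tags
    num <- function(tag) {
      v <- tags[[tag]]
      if (is.null(v)) NA_real_ else as.double(v)
    }
    rows[[length(rows) + 1L]] <- tibble(
      mol_id = parsed$mol_id,
      smiles = tags[["SMILES"]] %||% NA_character_,
      delta_exp = num("P31_SHIFT_EXP_PPM"),
      solvent = tags[["P31_SOLVENT_EXP"]] %||% "unknown"
    )
    extras[[parsed$mol_id]] <- tags[setdiff(names(tags), SDF_KNOWN_TAGS)]
    if (!is.na(num("P31_SHIFT_VAC_PPM")) || !is.na(num("P31_SHIFT_BOLTZMANN_PPM"))) {
      preds[[length(preds) + 1L]] <- tibble(
        mol_id = parsed$mol_id, condition = "vac",
        delta_single = num("P31_SHIFT_VAC_PPM"),
        delta_boltzmann = num("P31_SHIFT_BOLTZMANN_PPM")
      )
    }
    for (sv in CANONICAL_SOLVENTS) {
      v <- num(sdf_solvent_tag(sv))
      if (!is.na(v)) {
        preds[[length(preds) + 1L]] <- tibble(
          mol_id = parsed$mol_id, condition = sv,
          delta_single = v, delta_boltzmann = NA_real_
        )
      }
    }
  }
  if (skipped) warn(sprintf("Skipped %d malformed SDF entr(y/ies).", skipped))
  if (length(rows) == 0L) abort(sprintf("No valid SDF entries in %s", path))
  records <- suppressMessages(as_molecule_table(dplyr::bind_rows(rows)))
  records$extra_tags <- unname(extras[records$mol_id])
  predictions <- if (length(preds)) {
    dplyr::bind_rows(preds)
  } else {
    tibble(
      mol_id = character(), condition = character(),
      delta_single = double(), delta_boltzmann = double()
    )
  }
  list(records = records, predictions = predictions)
}

parse_sdf_entry <- function(entry) {
  if (length(entry) < 5L) abort("Truncated SDF entry.")
  mol_id <- trimws(entry[1])
  if (!nzchar(mol_id)) abort("SDF entry lacks a title (mol_id).")
  n_at <- suppressWarnings(as.integer(substr(entry[4], 1, 3)))
  n_bd <- suppressWarnings(as.integer(substr(entry[4], 4, 6)))
  mend <- which(startsWith(entry, "M  END"))
  if (is.na(n_at) || is.na(n_bd) || length(mend) == 0L ||
    mend[1] < 4L + n_at + n_bd) {
    abort("Malformed V2000 molecule block.")
  }
  tag_idx <- grep("^>\\s*<", entry)
  tags <- list()
  for (ti in tag_idx) {
    tag <- sub("^>\\s*<([^>]+)>.*$", "\\1", entry[ti])
    vals <- character()
    j <- ti + 1L
    while (j <= length(entry) && nzchar(trimws(entry[j])) &&
      !startsWith(entry[j], ">")) {
      vals <- c(vals, entry[j])
      j <- j + 1L
    }
    tags[[tag]] <- paste(vals, collapse = "\n")
  }
  list(mol_id = mol_id, tags = tags)
}
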
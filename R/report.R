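#' Stratified evaluation of shift predictions against experiment
#'
#' Computes error metrics per cohort and condition, and relative RMSE
#' improvements per cohort for each (reference, alternative) condition
#' pair. Cohorts follow the stratifications used for large shift
#' benchmarks: the whole data set, experimental solvent (unknown-solvent
#' records form their own cohort), molecule-size quantiles,
#' rotatable-bond quantiles and organophosphorus compound class.
#'
#' @param records A molecule table (see [as_molecule_table()]). Records
#'   without `delta_exp` are excluded, with the count reported in the
#'   result.
#' @param shifts A long tibble of calculated shifts: `mol_id`, `condition`,
#'   `delta_calc` (ppm). See [build_shift_series()] for deriving one from
#'   pipeline predictions.
#' @param condition_pairs List of `c(reference, alternative)` condition
#'   label pairs to compare by relative RMSE improvement.
#' @param by Cohort stratifications to compute.
#' @param shift_range Shift range (ppm) for the relative MAE.
#' @param k Number of quantile cohorts.
#' @return An object of class `p31_report`: a list with
#'   \describe{
#'     \item{metrics}{tibble of `cohort_kind`, `cohort`, `condition`, `n`,
#'       `rmse`, `mae`, `mse`, `rel_mae`, `mean_delta_exp`,
#'       `mean_delta_calc`}
#'     \item{improvements}{tibble of `cohort_kind`, `cohort`, `n`,
#'       `reference`, `alternative`, `rmse_reference`, `rmse_alternative`,
#'       `improvement_pct`}
#'     \item{n_excluded}{records dropped for missing `delta_exp`}
#'   }
#' @export
stratified_report <- function(records, shifts,
                              condition_pairs = list(),
                              by = c(
                                "all", "solvent", "size_quantile",
                                "rotatable_quantile", "class"
                              ),
                              shift_range = 698, k = 5L) {
  by <- match.arg(by, several.ok = TRUE)
  shifts <- as_tibble(shifts)
  if (!all(c("mol_id", "condition", "delta_calc") %in% names(shifts))) {
    abort("`shifts` needs columns mol_id, condition, delta_calc.")
  }
  usable <- records[!is.na(records$delta_exp), , drop = FALSE]
  n_excluded <- nrow(records) - nrow(usable)
  if (n_excluded > 0) {
    inform(sprintf("Excluded %d record(s) without experimental shift.", n_excluded))
  }
  if (nrow(usable) == 0L) abort("No records with experimental shifts to evaluate.")

  membership <- dplyr::bind_rows(purrr::map(by, function(kind) {
    switch(kind,
      all = tibble(cohort_kind = "all", cohort = "all", mol_id = usable$mol_id),
      solvent = tibble(
        cohort_kind = "solvent", cohort = usable$solvent, mol_id = usable$mol_id
      ),
      size_quantile = {
        q <- quantile_split(usable, "n_atoms", k = min(k, nrow(usable)))
        tibble(
          cohort_kind = "size_quantile",
          cohort = sprintf("%s [%d-%d]", q$cohort, q$value_min, q$value_max),
          mol_id = q$mol_id
        )
      },
      rotatable_quantile = {
        q <- quantile_split(usable, "n_rotatable_bonds", k = min(k, nrow(usable)))
        tibble(
          cohort_kind = "rotatable_quantile",
          cohort = sprintf("%s [%d-%d]", q$cohort, q$value_min, q$value_max),
          mol_id = q$mol_id
        )
      },
      class = tibble(
        cohort_kind = "class", cohort = usable$class_label, mol_id = usable$mol_id
      )
    )
  }))

  paired <- dplyr::inner_join(
    membership,
    dplyr::inner_join(
      shifts,
      usable[, c("mol_id", "delta_exp")],
      by = "mol_id"
    ),
    by = "mol_id",
    relationship = "many-to-many"
  )
  paired <- paired[!is.na(paired$delta_calc), , drop = FALSE]

  empty <- setdiff(
    unique(paste(membership$cohort_kind, membership$cohort)),
    unique(paste(paired$cohort_kind, paired$cohort))
  )
  if (length(empty)) {
    warn(sprintf(
      "Dropping cohort(s) without evaluable predictions: %s",
      paste(empty, collapse = "; ")
    ))
  }

  metrics <- paired |>
    dplyr::group_by(.data$cohort_kind, .data$cohort, .data$condition) |>
    dplyr::summarise(
      metrics = compute_error_metrics(
        .data$delta_exp, .data$delta_calc,
        shift_range = shift_range
      ),
      mean_delta_exp = mean(.data$delta_exp),
      mean_delta_calc = mean(.data$delta_calc),
      .groups = "drop"
    ) |>
    tidyr::unpack("metrics") |>
    dplyr::relocate("n", .after = "condition")

  improvements <- dplyr::bind_rows(purrr::map(condition_pairs, function(pair) {
    ref <- metrics[metrics$condition == pair[1], ]
    alt <- metrics[metrics$condition == pair[2], ]
    j <- dplyr::inner_join(
      ref[, c("cohort_kind", "cohort", "n", "rmse")],
      alt[, c("cohort_kind", "cohort", "rmse")],
      by = c("cohort_kind", "cohort"), suffix = c("_reference", "_alternative")
    )
    if (nrow(j) == 0L) return(NULL)
    tibble(
      cohort_kind = j$cohort_kind, cohort = j$cohort, n = j$n,
      reference = pair[1], alternative = pair[2],
      rmse_reference = j$rmse_reference,
      rmse_alternative = j$rmse_alternative,
      # a perfect reference admits no relative improvement: 0 when the
      # alternative is also perfect, undefined (NA) when it is worse
      improvement_pct = dplyr::case_when(
        j$rmse_reference > 0 ~
          100 * (j$rmse_reference - j$rmse_alternative) / j$rmse_reference,
        j$rmse_alternative == 0 ~ 0,
        TRUE ~ NA_real_
      )
    )
  }))

  structure(
    list(
      metrics = metrics,
      improvements = improvements,
      n_excluded = n_excluded,
      shift_range = shift_range
    ),
    class = "p31_report"
  )
}

#' @export
print.p31_report <- function(x, ...) {
  cat("<p31_report>\n")
  cat(sprintf(
    "  %d cohort x condition metric rows (shift range %.0f ppm, %d record(s) excluded)\n",
    nrow(x$metrics), x$shift_range, x$n_excluded
  ))
  shown <- x$metrics
  shown$rmse <- round_half_up(shown$rmse, 2)
  shown$mae <- round_half_up(shown$mae, 2)
  shown$mse <- round_half_up(shown$mse, 2)
  shown$rel_mae <- round_half_up(shown$rel_mae, 1)
  print(shown[, c("cohort_kind", "cohort", "condition", "n", "rmse", "mae", "mse", "rel_mae")],
    n = 20
  )
  if (!is.null(x$improvements) && nrow(x$improvements)) {
    cat("  improvements (reference -> alternative, % of reference RMSE):\n")
    imp <- x$improvements
    imp$improvement_pct <- round_half_up(imp$improvement_pct, 1)
    print(imp[, c("cohort_kind", "cohort", "n", "reference", "alternative", "improvement_pct")],
      n = 20
    )
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname stratified_report
#' @param x A `p31_report`.
#' @param ... Unused.
#' @export
tidy.p31_report <- function(x, ...) x$metrics

#' @rdname stratified_report
#' @export
glance.p31_report <- function(x, ...) {
  overall <- x$metrics[x$metrics$cohort_kind == "all", , drop = FALSE]
  if (nrow(overall) == 0L) overall <- x$metrics
  best <- overall[which.min(overall$rmse), ]
  tibble(
    n = max(x$metrics$n),
    n_conditions = length(unique(x$metrics$condition)),
    n_cohorts = nrow(unique(x$metrics[, c("cohort_kind", "cohort")])),
    best_condition = best$condition,
    best_rmse = best$rmse,
    n_excluded = x$n_excluded
  )
}

#' Write a report's tables to CSV
#'
#' @param report A `p31_report`.
#' @param metrics_path,improvements_path Output CSV paths (either may be
#'   `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_report_csv <- function(report, metrics_path = NULL, improvements_path = NULL) {
  stopifnot(inherits(report, "p31_report"))
  if (!is.null(metrics_path)) {
    readr::write_csv(report$metrics, metrics_path, progress = FALSE)
  }
  if (!is.null(improvements_path) && !is.null(report$improvements)) {
    readr::write_csv(report$improvements, improvements_path, progress = FALSE)
  }
  invisible(report)
}
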
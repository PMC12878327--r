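#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot experimental versus calculated shifts
#'
#' A pairs-style agreement plot of calculated against experimental
#' phosphorus-31 shifts, one facet per evaluation condition, with the
#' identity line.
#'
#' @param records A molecule table with `delta_exp`.
#' @param shifts A long shift series (`mol_id`, `condition`, `delta_calc`),
#'   e.g. from [build_shift_series()].
#' @return A ggplot object.
#' @export
plot_shift_agreement <- function(records, shifts) {
  df <- dplyr::inner_join(
    shifts, records[, c("mol_id", "delta_exp")],
    by = "mol_id"
  )
  df <- df[!is.na(df$delta_exp) & !is.na(df$delta_calc), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_exp, y = .data$delta_calc)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(
      x = expression(delta[exp] ~ "(ppm)"),
      y = expression(delta[calc] ~ "(ppm)")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname stratified_report
#' @param object A `p31_report` (or `p31_pipeline`).
#' @export
autoplot.p31_report <- function(object, ...) {
  imp <- object$improvements
  if (is.null(imp) || nrow(imp) == 0L) {
    met <- object$metrics
    return(
      ggplot2::ggplot(met, ggplot2::aes(
        x = .data$cohort, y = .data$rmse,
        fill = .data$condition
      )) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::facet_wrap(ggplot2::vars(.data$cohort_kind), scales = "free_x") +
        ggplot2::labs(x = NULL, y = "RMSE (ppm)") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    )
  }
  imp$pair <- paste(imp$reference, "→", imp$alternative)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$cohort, y = .data$improvement_pct,
    fill = .data$pair
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$cohort_kind), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "RMSE improvement (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname run_pipeline
#' @param object A `p31_pipeline`.
#' @export
autoplot.p31_pipeline <- function(object, ...) {
  plot_shift_agreement(object$records, object$shifts)
}
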
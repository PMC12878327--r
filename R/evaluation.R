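#' Error metrics between experimental and calculated shifts
#'
#' Root-mean-square error, mean absolute error and mean signed error over
#' paired shifts, with the signed error fixed as `delta_exp - delta_calc`
#' (negative MSE therefore means the calculation overestimates shifts).
#' The relative MAE normalizes the MAE by the data set's shift range, by
#' default the 698 ppm span of phosphorus-31 shifts.
#'
#' @param delta_exp,delta_calc Paired experimental and calculated shifts
#'   (ppm); no missing values, at least one pair.
#' @param shift_range Shift range used for the relative MAE (ppm, > 0).
#' @return A one-row tibble: `n`, `rmse`, `mae`, `mse` (ppm) and `rel_mae`
#'   (percent). All values at full precision; round for reporting.
#' @examples
#' compute_error_metrics(c(0, 0), c(1, -1)) # rmse = mae = 1, mse = 0
#' @export
compute_error_metrics <- function(delta_exp, delta_calc, shift_range = 698) {
  if (length(delta_exp) == 0L) abort("At least one (exp, calc) pair is required.")
  if (length(delta_exp) != length(delta_calc)) {
    abort("`delta_exp` and `delta_calc` must have equal length.")
  }
  if (anyNA(delta_exp) || anyNA(delta_calc)) {
    abort("Missing shift values: filter incomplete pairs before computing metrics.")
  }
  stopifnot_scalar_number(shift_range, "shift_range", positive = TRUE)
  err <- delta_exp - delta_calc
  mae <- mean(abs(err))
  tibble(
    n = length(err),
    rmse = sqrt(mean(err^2)),
    mae = mae,
    mse = mean(err),
    rel_mae = 100 * mae / shift_range
  )
}

#' Relative improvement between two RMSE values
#'
#' `100 * (rmse_reference - rmse_alternative) / rmse_reference`: positive
#' when the alternative condition predicts better than the reference,
#' negative when it is worse. Returned at full precision; printed tables
#' round to one decimal.
#'
#' @param rmse_reference RMSE of the reference condition (ppm, > 0).
#' @param rmse_alternative RMSE of the alternative condition (ppm).
#' @return Improvement in percent.
#' @examples
#' improvement_percent(30.82, 29.37) # 4.7 at one decimal
#' @export
improvement_percent <- function(rmse_reference, rmse_alternative) {
  if (any(!is.finite(rmse_reference)) || any(rmse_reference <= 0)) {
    abort("`rmse_reference` must be > 0.")
  }
  100 * (rmse_reference - rmse_alternative) / rmse_reference
}

#' Split molecules into equal-size quantile cohorts
#'
#' Sorts records ascending by the chosen key (ties broken by `mol_id` so
#' the split is reproducible) and cuts them into `k` contiguous cohorts
#' whose sizes differ by at most one, larger cohorts first. 10,007 records
#' in 5 cohorts therefore give sizes 2002/2002/2001/2001/2001.
#'
#' @param records A molecule table.
#' @param key `"n_atoms"` or `"n_rotatable_bonds"`.
#' @param k Number of cohorts.
#' @return A tibble with one row per record: `mol_id`, `cohort`
#'   (`"Q1"`..`"Qk"`), `value` (the key), plus per-cohort `value_min`,
#'   `value_max`.
#' @export
quantile_split <- function(records, key = c("n_atoms", "n_rotatable_bonds"),
                           k = 5L) {
  key <- match.arg(key)
  if (!is.numeric(k) || length(k) != 1L || k < 1) abort("`k` must be a count >= 1.")
  k <- as.integer(k)
  n <- nrow(records)
  if (n < k) abort(sprintf("Cannot split %d records into %d quantiles.", n, k))
  ord <- order(records[[key]], records$mol_id)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  cohort <- rep(sprintf("Q%d", seq_len(k)), times = sizes)
  out <- tibble(
    mol_id = records$mol_id[ord],
    cohort = cohort,
    value = records[[key]][ord]
  )
  dplyr::mutate(
    dplyr::group_by(out, .data$cohort),
    value_min = min(.data$value), value_max = max(.data$value),
    .keep = "all"
  ) |> dplyr::ungroup()
}

#' Classify an organophosphorus molecule by phosphorus substitution pattern
#'
#' Matches the phosphorus environment against four generic classes (R =
#' carbon substituent, OR = ester oxygen bound to carbon):
#' \describe{
#'   \item{phosphonate}{`R-P(=O)(OR)2` - one C, one =O, two O-C, no P-H}
#'   \item{dialkyl_phosphinate}{`R2-P(=O)OR` - two C, one =O, one O-C}
#'   \item{monoalkyl_phosphinate}{`R-P(=O)(H)OR` - one C, one =O, one O-C, one P-H}
#'   \item{phosphonite}{`R-P(OR)2` - one C, two O-C, no =O, no P-H}
#' }
#' Connectivity must match exactly (no additional substituents on P).
#' Classes are tested in the fixed priority order above; molecules with
#' several phosphorus atoms are assigned the first class any of them
#' matches. Everything else, trimethylphosphine included, is `"other"`.
#'
#' @param smiles A single SMILES string containing at least one phosphorus.
#' @return One of `"phosphonate"`, `"dialkyl_phosphinate"`,
#'   `"monoalkyl_phosphinate"`, `"phosphonite"`, `"other"`.
#' @examples
#' classify_p_class("CCP(=O)(OCC)OCC") # phosphonate
#' classify_p_class("CP(C)C")          # other
#' @export
classify_p_class <- function(smiles) {
  g <- parse_smiles(smiles)
  p_atoms <- which(g$atoms$element == "P")
  if (length(p_atoms) == 0L) abort("SMILES contains no phosphorus atom.")
  envs <- lapply(p_atoms, function(p) p_environment(g, p))
  matches <- function(f) any(vapply(envs, f, logical(1)))
  if (matches(function(e) e$n_c == 1 && e$n_odbl == 1 && e$n_oc == 2 && e$n_h == 0 && e$n_other == 0)) {
    return("phosphonate")
  }
  if (matches(function(e) e$n_c == 2 && e$n_odbl == 1 && e$n_oc == 1 && e$n_h == 0 && e$n_other == 0)) {
    return("dialkyl_phosphinate")
  }
  if (matches(function(e) e$n_c == 1 && e$n_odbl == 1 && e$n_oc == 1 && e$n_h == 1 && e$n_other == 0)) {
    return("monoalkyl_phosphinate")
  }
  if (matches(function(e) e$n_c == 1 && e$n_odbl == 0 && e$n_oc == 2 && e$n_h == 0 && e$n_other == 0)) {
    return("phosphonite")
  }
  "other"
}

p_environment <- function(g, p) {
  b <- g$bonds
  nb_idx <- c(b$to[b$from == p], b$from[b$to == p])
  nb_order <- c(b$order[b$from == p], b$order[b$to == p])
  el <- g$atoms$element[nb_idx]
  has_carbon <- function(o) {
    onb <- setdiff(c(b$to[b$from == o], b$from[b$to == o]), p)
    any(g$atoms$element[onb] == "C")
  }
  is_odbl <- el == "O" & nb_order == 2
  is_oc <- el == "O" & nb_order == 1 &
    vapply(nb_idx, has_carbon, logical(1))
  is_c <- el == "C" & nb_order == 1
  list(
    n_c = sum(is_c),
    n_odbl = sum(is_odbl),
    n_oc = sum(is_oc),
    n_h = g$atoms$n_h[p],
    n_other = sum(!(is_c | is_odbl | is_oc))
  )
}
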
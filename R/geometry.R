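#' Root-mean-square deviation after optimal superposition
#'
#' Computes the Kabsch RMSD between two conformations of the same molecule:
#' both coordinate sets are translated to their centroids, the rotation
#' minimizing the summed squared deviation is found from the SVD of the
#' covariance matrix, and mirror images are excluded by forcing the
#' rotation's determinant to +1. Atom ordering is assumed identical; no
#' symmetry-equivalent atom permutation is attempted.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (Angstrom), identical
#'   atom ordering, N >= 3.
#' @return The RMSD in Angstrom (non-negative, symmetric in its arguments).
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' kabsch_rmsd(a, a) # 0
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L) {
    abort("Coordinate sets must be N x 3 matrices of equal dimension.")
  }
  if (nrow(a) < 3L) {
    abort("At least 3 atoms are required: the optimal rotation is under-determined below that.")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) abort("Coordinates must be finite.")
  n <- nrow(a)
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  h <- crossprod(a, b)
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  # apply the optimal rotation and measure the residual directly: the
  # closed-form trace expression cancels catastrophically near zero
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sqrt(sum((a %*% rot - b)^2) / n)
}

#' Pruning configuration for conformer ensembles
#'
#' Defaults follow the ensemble workflow this package implements: thermally
#' accessible conformers within a 6 kcal/mol Gibbs-energy window, greedy
#' RMSD-based pruning at 0.5 Angstrom, and at most 20 conformers retained
#' for shielding calculations.
#'
#' @param rmsd_threshold Minimum pairwise RMSD (Angstrom) between retained
#'   conformers; a candidate is added only if it exceeds this against every
#'   already-selected conformer.
#' @param max_conformers Maximum ensemble size after pruning.
#' @param energy_window Gibbs-energy window in kcal/mol (inclusive).
#' @return A list of class `prune_config`.
#' @export
prune_config <- function(rmsd_threshold = 0.5, max_conformers = 20L,
                         energy_window = 6.0) {
  stopifnot_scalar_number(rmsd_threshold, "rmsd_threshold", positive = TRUE)
  stopifnot_scalar_number(energy_window, "energy_window", positive = TRUE)
  if (!is.numeric(max_conformers) || length(max_conformers) != 1L ||
    max_conformers < 1) {
    abort("`max_conformers` must be a single count >= 1.")
  }
  structure(
    list(
      rmsd_threshold = rmsd_threshold,
      max_conformers = as.integer(max_conformers),
      energy_window = energy_window
    ),
    class = "prune_config"
  )
}

#' Keep conformers inside a Gibbs-energy window
#'
#' Retains conformers with relative Gibbs energy at or below `window`
#' (inclusive boundary). The lowest-energy conformer has delta_G = 0 and is
#' always retained, so the result is never empty. Order is preserved.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param window Energy window in kcal/mol.
#' @return A [conformer_ensemble()] restricted to the window.
#' @export
filter_energy_window <- function(ensemble, window = 6.0) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  stopifnot_scalar_number(window, "window", positive = TRUE)
  keep <- ensemble$conformers$delta_G <= window
  set_conformers(ensemble, ensemble$conformers[keep, , drop = FALSE])
}

#' Prune a conformer ensemble by greedy RMSD selection
#'
#' When an ensemble holds more conformers than `max_conformers`, candidates
#' are visited in ascending energy order (ties broken by `conf_id`),
#' starting from the lowest-energy conformer, which is always selected
#' first. A candidate is added if and only if its minimum RMSD against all
#' already-selected conformers is strictly greater than `rmsd_threshold`;
#' selection stops once `max_conformers` are retained or the candidates are
#' exhausted (no threshold relaxation is attempted). Ensembles already at
#' or below `max_conformers` are returned unchanged.
#'
#' @param ensemble A [conformer_ensemble()], typically already restricted
#'   with [filter_energy_window()].
#' @param config A [prune_config()].
#' @return The pruned [conformer_ensemble()], sorted by energy.
#' @export
prune_ensemble <- function(ensemble, config = prune_config()) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  stopifnot(inherits(config, "prune_config"))
  conf <- ensemble$conformers
  if (nrow(conf) <= config$max_conformers) {
    return(ensemble)
  }
  ord <- order(conf$delta_G, conf$conf_id)
  conf <- conf[ord, , drop = FALSE]
  selected <- 1L
  for (k in seq_len(nrow(conf))[-1]) {
    if (length(selected) >= config$max_conformers) break
    min_rmsd <- min(vapply(
      selected,
      function(s) kabsch_rmsd(conf$coords[[s]], conf$coords[[k]]),
      double(1)
    ))
    if (min_rmsd > config$rmsd_threshold) selected <- c(selected, k)
  }
  set_conformers(ensemble, conf[selected, , drop = FALSE])
}
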
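#' Construct a conformer ensemble
#'
#' A conformer ensemble holds, for one molecule, an ordered set of 3D
#' geometries with relative Gibbs energies (kcal/mol) and, once a shielding
#' backend has run, per-conformer isotropic phosphorus shieldings (ppm).
#' Energies are shifted so the minimum is exactly 0, matching the convention
#' that Gibbs energies are relative to the most stable conformer.
#'
#' @param mol_id Molecule identifier.
#' @param coords List of N x 3 coordinate matrices (Angstrom), one per
#'   conformer, all with the same atom count and ordering.
#' @param delta_G Numeric vector of relative Gibbs energies, kcal/mol.
#' @param conf_id Optional conformer identifiers (default `c001`, ...).
#' @param sigma_P Optional per-conformer isotropic shieldings at phosphorus
#'   (ppm): a numeric vector, or a list of numeric vectors for molecules
#'   with several symmetry-equivalent phosphorus atoms.
#' @param elements Optional character vector of element symbols, one per
#'   atom row of the coordinate matrices.
#' @param temperature Ensemble temperature in K (default 298.15).
#' @return An object of class `conformer_ensemble`: a list with `mol_id`,
#'   `elements`, `temperature` and a `conformers` tibble
#'   (`conf_id`, `delta_G`, `sigma_P`, `coords` list-column).
#' @export
conformer_ensemble <- function(mol_id, coords, delta_G,
                               conf_id = NULL, sigma_P = NULL,
                               elements = NULL, temperature = 298.15) {
  if (!is.list(coords) || length(coords) == 0L) {
    abort("`coords` must be a nonempty list of N x 3 matrices.")
  }
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L || !all(is.finite(m))) {
      abort("Each conformer geometry must be a finite N x 3 matrix.")
    }
    dimnames(m) <- NULL
    m
  })
  n_atoms <- vapply(coords, nrow, integer(1))
  if (length(unique(n_atoms)) != 1L) {
    abort("All conformers must share the same atom count.")
  }
  if (n_atoms[1] < 2L) abort("A conformer needs at least 2 atoms.")
  if (length(delta_G) != length(coords)) {
    abort("`delta_G` must have one value per conformer.")
  }
  if (!all(is.finite(delta_G))) abort("`delta_G` must be finite.")
  stopifnot_scalar_number(temperature, "temperature", positive = TRUE)
  delta_G <- as.double(delta_G) - min(delta_G)

  if (is.null(conf_id)) conf_id <- sprintf("c%03d", seq_along(coords))
  conf_id <- as.character(conf_id)
  if (anyDuplicated(conf_id)) abort("`conf_id` values must be unique.")
  if (is.null(sigma_P)) sigma_P <- rep(NA_real_, length(coords))

  if (!is.null(elements) && length(elements) != n_atoms[1]) {
    abort("`elements` must have one symbol per atom.")
  }

  structure(
    list(
      mol_id = as.character(mol_id),
      elements = elements,
      temperature = temperature,
      conformers = tibble(
        conf_id = conf_id,
        delta_G = delta_G,
        sigma_P = sigma_P,
        coords = coords
      )
    ),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conformer_ensemble> %s: %d conformer(s), %d atoms, T = %.2f K\n",
    x$mol_id, nrow(x$conformers), nrow(x$conformers$coords[[1]]), x$temperature
  ))
  cat(sprintf(
    "  delta_G [kcal/mol]: %s\n",
    paste(sprintf("%.2f", utils::head(x$conformers$delta_G, 8)), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname conformer_ensemble
#' @param x A `conformer_ensemble`.
#' @export
n_conformers <- function(x) {
  stopifnot(inherits(x, "conformer_ensemble"))
  nrow(x$conformers)
}

# Replace the conformer tibble, keeping class/metadata and re-normalizing
# energies so the minimum stays exactly 0.
set_conformers <- function(ensemble, conformers) {
  ensemble$conformers <- conformers
  ensemble$conformers$delta_G <- conformers$delta_G - min(conformers$delta_G)
  ensemble
}

#' Read a multi-conformer XYZ file
#'
#' Reads concatenated XYZ blocks. Each block's comment line must carry a
#' `dG=<value>` token (relative Gibbs energy, kcal/mol) and may carry a
#' `conf=<id>` token. Energies are shifted so the minimum is exactly 0;
#' conformer order is preserved.
#'
#' @param path Path to the XYZ file.
#' @param mol_id Molecule identifier; defaults to the file name without
#'   extension.
#' @param temperature Ensemble temperature in K.
#' @return A [conformer_ensemble()].
#' @export
read_conformer_xyz <- function(path, mol_id = NULL, temperature = 298.15) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (is.null(mol_id)) mol_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)

  coords <- list()
  delta_G <- double()
  conf_id <- character()
  elements <- NULL
  i <- 1L
  block <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      abort(sprintf("Line %d: expected an atom count, got '%s'.", i, lines[i]))
    }
    if (i + 1L + n > length(lines)) abort("Truncated XYZ block at end of file.")
    block <- block + 1L
    comment <- lines[i + 1L]
    m <- regmatches(comment, regexec("dG=\\s*(-?[0-9.eE+-]+)", comment))[[1]]
    if (length(m) == 0L) {
      abort(sprintf("XYZ block %d: comment line lacks a 'dG=<value>' token.", block))
    }
    dg <- as.double(m[2])
    cm <- regmatches(comment, regexec("conf=\\s*(\\S+)", comment))[[1]]
    cid <- if (length(cm)) cm[2] else sprintf("c%03d", block)

    atom_lines <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    if (any(lengths(atom_lines) < 4L)) {
      abort(sprintf("XYZ block %d: malformed atom line.", block))
    }
    el <- vapply(atom_lines, `[`, character(1), 1)
    xyz <- t(vapply(
      atom_lines,
      function(f) as.double(f[2:4]),
      double(3)
    ))
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements)) {
      abort(sprintf(
        "XYZ block %d has %d atoms but block 1 has %d: atom counts must match.",
        block, length(el), length(elements)
      ))
    }
    coords[[block]] <- xyz
    delta_G <- c(delta_G, dg)
    conf_id <- c(conf_id, cid)
    i <- i + 2L + n
  }
  if (block == 0L) abort(sprintf("No XYZ blocks found in %s", path))
  conformer_ensemble(
    mol_id = mol_id, coords = coords, delta_G = delta_G,
    conf_id = conf_id, elements = elements, temperature = temperature
  )
}

#' Write a conformer ensemble as multi-block XYZ
#'
#' @param ensemble A [conformer_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conformer_xyz <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  el <- ensemble$elements
  if (is.null(el)) el <- rep("X", nrow(ensemble$conformers$coords[[1]]))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(ensemble$conformers))) {
    xyz <- ensemble$conformers$coords[[k]]
    writeLines(as.character(nrow(xyz)), con)
    writeLines(
      sprintf(
        "conf=%s dG=%.6f", ensemble$conformers$conf_id[k],
        ensemble$conformers$delta_G[k]
      ),
      con
    )
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", el, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
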
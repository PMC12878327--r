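#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Round half away from zero, as printed tables do (round() in R rounds half
# to even, which would turn 2.25 into 2.2).
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# Derive a per-unit seed from one master seed and a counter, so that each
# molecule owns an independent, order-insensitive random stream. Kept below
# 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, counter) {
  m <- 2147483647
  s <- (as.double(seed) %% m) * 48271 %% m
  as.integer((s + as.double(counter) * 1103515245 + 12345) %% m)
}

# Deterministic pseudo-uniform value in [-1, 1] keyed on a numeric vector
# (used to give each conformer geometry a reproducible shielding
# perturbation without consuming the RNG stream).
hash_unit <- function(x) {
  v <- round(as.double(x) * 1e3)
  k <- seq_along(v)
  s <- sum(sin(v * 12.9898 + k * 78.233)) * 43758.5453
  2 * (s - floor(s)) - 1
}

# Named-vector lookup that treats absent names as 0 (partial offset maps
# are allowed everywhere offsets are configured).
lookup_or_zero <- function(x, name) {
  if (!is.null(x) && name %in% names(x)) x[[name]] else 0
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
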
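# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: RMSD via Horn's quaternion method and via
# numeric minimization over Euler angles, and a from-scratch re-statement
# of the greedy pruning rule.

center_rows <- function(m) sweep(m, 2, colMeans(m))

# Horn (1987) closed-form superposition RMSD: maximum eigenvalue of the
# 4x4 quaternion matrix; proper rotations only.
horn_rmsd <- function(a, b) {
  a <- center_rows(as.matrix(a))
  b <- center_rows(as.matrix(b))
  s <- crossprod(a, b)
  k <- matrix(c(
    s[1, 1] + s[2, 2] + s[3, 3], s[2, 3] - s[3, 2], s[3, 1] - s[1, 3], s[1, 2] - s[2, 1],
    s[2, 3] - s[3, 2], s[1, 1] - s[2, 2] - s[3, 3], s[1, 2] + s[2, 1], s[3, 1] + s[1, 3],
    s[3, 1] - s[1, 3], s[1, 2] + s[2, 1], -s[1, 1] + s[2, 2] - s[3, 3], s[2, 3] + s[3, 2],
    s[1, 2] - s[2, 1], s[3, 1] + s[1, 3], s[2, 3] + s[3, 2], -s[1, 1] - s[2, 2] + s[3, 3]
  ), 4, 4)
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(sum(a^2) + sum(b^2) - 2 * lambda, 0) / nrow(a))
}

euler_rotation <- function(ang) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  rz(ang[1]) %*% ry(ang[2]) %*% rz(ang[3])
}

# Multi-start numeric minimization over rotation angles; slow but
# assumption-free.
numeric_rmsd <- function(a, b, n_starts = 24) {
  a <- center_rows(as.matrix(a))
  b <- center_rows(as.matrix(b))
  obj <- function(ang) sum((a %*% euler_rotation(ang) - b)^2)
  best <- Inf
  for (s in seq_len(n_starts)) {
    start <- stats::runif(3, -pi, pi)
    fit <- stats::optim(start, obj, method = "BFGS", control = list(maxit = 500))
    best <- min(best, fit$value)
  }
  sqrt(best / nrow(a))
}

random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Brute-force restatement of the greedy pruning rule on raw conformer
# tables, using the Horn oracle for RMSD.
prune_oracle_ids <- function(ensemble, threshold = 0.5, max_keep = 20L) {
  conf <- ensemble$conformers
  if (nrow(conf) <= max_keep) {
    return(conf$conf_id)
  }
  ord <- order(conf$delta_G, conf$conf_id)
  ids <- conf$conf_id[ord]
  coords <- conf$coords[ord]
  sel <- 1L
  for (k in seq_along(ids)[-1]) {
    if (length(sel) >= max_keep) break
    dmin <- min(vapply(sel, function(s) horn_rmsd(coords[[s]], coords[[k]]), double(1)))
    if (dmin > threshold) sel <- c(sel, k)
  }
  ids[sel]
}
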
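# Independent oracles used across the suite.

# Grid of random rotations (unit quaternions) as an n x 9 matrix whose rows
# hold R11,R12,...,R33 (row-major).
quat_rotation_grid <- function(n, seed = 424242) {
  set.seed(seed)
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

# Brute-force minimum RMSD over a rotation grid: for centered sets,
# rmsd^2 = (|A|^2 + |B|^2 - 2 tr(R^T H)) / n with H = A0^T B0.
oracle_min_rmsd <- function(A, B, grid) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  H <- crossprod(A0, B0)
  tv <- grid %*% as.vector(t(H))
  c2 <- sum(A0^2) + sum(B0^2)
  sqrt(max(0, (c2 - 2 * max(tv)) / nrow(A)))
}

# rotation by `deg` about z as used to build rigid-motion fixtures
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
}
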
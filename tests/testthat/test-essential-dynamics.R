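test_that("static ensembles have all-zero eigenvalues", {
  topo <- bead_topology(4)
  ref <- matrix(rnorm(12), 4, 3)
  stat <- manual_ensemble(topo, list(ref, ref, ref))
  suppressWarnings(md <- compute_modes(stat, analysis_window(0)))
  expect_equal(md$eigenvalues, rep(0, 12), tolerance = 1e-12)
})

test_that("an injected unit mode is recovered in direction and variance", {
  set.seed(6)
  nb <- 30; nf <- 4000; A <- 3; sigma <- 0.3
  topo <- bead_topology(nb)
  ref <- matrix(rnorm(nb * 3, sd = 10), nb, 3)
  u <- rnorm(3 * nb); u <- u / sqrt(sum(u^2))
  umat <- matrix(u, nb, 3, byrow = TRUE)
  coords <- array(0, dim = c(nf, nb, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- ref + A * sin(2 * pi * f / 100) * umat +
      matrix(rnorm(nb * 3, sd = sigma), nb, 3)
  }
  ens <- trajectory_ensemble(topo, list(coords), 10)
  md <- compute_modes(ens, analysis_window(0))
  expect_gt(abs(sum(md$eigenvectors[, 1] * u)), 0.99)
  expect_equal(md$eigenvalues[1], A^2 / 2 + sigma^2, tolerance = 0.1 * (A^2 / 2 + sigma^2))
})

test_that("eigenpairs match an independent SVD-based oracle on a toy case", {
  set.seed(23)
  topo <- bead_topology(4)
  frames <- lapply(1:6, function(i) matrix(rnorm(12, sd = 2), 4, 3))
  ens <- manual_ensemble(topo, frames)
  suppressWarnings(md <- compute_modes(ens, analysis_window(0)))

  # oracle: flatten frames the same way, SVD of the centered data matrix
  X <- t(vapply(frames, function(m) as.vector(t(m)), numeric(12)))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  lam_oracle <- sv$d^2 / nrow(X)
  expect_equal(md$eigenvalues[1:5], lam_oracle[1:5], tolerance = 1e-8)
  for (j in 1:3) {
    expect_equal(abs(sum(md$eigenvectors[, j] * sv$v[, j])), 1,
                 tolerance = 1e-8)
  }
  # orthonormality
  G <- crossprod(md$eigenvectors)
  expect_equal(G, diag(12), tolerance = 1e-8)
  # total variance is conserved
  expect_equal(sum(md$eigenvalues), sum(Xc^2) / nrow(X), tolerance = 1e-8)
})

test_that("projections satisfy exactness and Parseval completeness", {
  set.seed(29)
  topo <- bead_topology(4)
  frames <- lapply(1:8, function(i) matrix(rnorm(12, sd = 2), 4, 3))
  ens <- manual_ensemble(topo, frames)
  suppressWarnings(md <- compute_modes(ens, analysis_window(0)))

  # frame equal to the mean structure projects to zero
  ens_mean <- manual_ensemble(topo, list(md$mean_structure, md$mean_structure))
  pr0 <- project_modes(ens_mean, md, 1:2)
  expect_equal(pr0$S1, c(0, 0), tolerance = 1e-10)

  # frame = mean + 2.5 v1 projects to exactly (2.5, 0)
  shift <- md$mean_structure + 2.5 * matrix(md$eigenvectors[, 1], 4, 3,
                                            byrow = TRUE)
  pr1 <- project_modes(manual_ensemble(topo, list(shift)), md, 1:2)
  expect_equal(pr1$S1, 2.5, tolerance = 1e-10)
  expect_equal(pr1$S2, 0, tolerance = 1e-10)

  # Parseval: sum_j S^2 = |X - mean|^2 with all 3N modes
  pr <- project_modes(ens, md, 1:12)
  S <- as.matrix(pr[, paste0("S", 1:12)])
  for (f in 1:8) {
    direct <- sum((as.vector(t(frames[[f]])) -
                   as.vector(t(md$mean_structure)))^2)
    expect_equal(sum(S[f, ]^2), direct, tolerance = 1e-6 * max(direct, 1))
  }

  expect_error(project_modes(ens, md, 13), "out of range")
})

test_that("modes are invariant to frame order and uniform translation", {
  set.seed(37)
  topo <- bead_topology(5)
  frames <- lapply(1:10, function(i) matrix(rnorm(15), 5, 3))
  ens <- manual_ensemble(topo, frames)
  suppressWarnings(md1 <- compute_modes(ens, analysis_window(0)))
  ens_rev <- manual_ensemble(topo, rev(frames))
  suppressWarnings(md2 <- compute_modes(ens_rev, analysis_window(0)))
  expect_equal(md1$eigenvalues, md2$eigenvalues, tolerance = 1e-10)

  shifted <- lapply(frames, function(m) sweep(m, 2, c(7, -3, 11), "+"))
  suppressWarnings(md3 <- compute_modes(manual_ensemble(topo, shifted),
                                        analysis_window(0)))
  expect_equal(md1$eigenvalues, md3$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(diag(crossprod(md1$eigenvectors[, 1:3],
                                  md3$eigenvectors[, 1:3]))),
               rep(1, 3), tolerance = 1e-8)
})

test_that("KDE landscape recovers moments of a known Gaussian", {
  set.seed(41)
  n <- 20000
  mu <- c(2, -1); sd <- c(1.5, 0.8)
  pr <- data.frame(S1 = rnorm(n, mu[1], sd[1]), S2 = rnorm(n, mu[2], sd[2]))
  ls <- estimate_landscape(pr, gridsize = 121)
  w <- ls$density / sum(ls$density)
  m1 <- sum(outer(ls$s1, rep(1, length(ls$s2))) * w)
  m2 <- sum(outer(rep(1, length(ls$s1)), ls$s2) * w)
  v1 <- sum(outer(ls$s1, rep(1, length(ls$s2)))^2 * w) - m1^2
  v2 <- sum(outer(rep(1, length(ls$s1)), ls$s2)^2 * w) - m2^2
  expect_equal(m1, mu[1], tolerance = 0.05)
  expect_equal(m2, mu[2], tolerance = 0.05)
  expect_lt(abs(v1 - sd[1]^2) / sd[1]^2, 0.05)
  expect_lt(abs(v2 - sd[2]^2) / sd[2]^2, 0.05)

  # density integrates to ~1 over the grid
  cell <- diff(ls$s1[1:2]) * diff(ls$s2[1:2])
  expect_equal(sum(ls$density) * cell, 1, tolerance = 0.02)
})

test_that("degenerate and compact-support samples behave as documented", {
  # single repeated point: delta-like peak at the point, with a warning
  pr <- data.frame(S1 = rep(1.5, 10), S2 = rep(-2, 10))
  expect_warning(ls <- estimate_landscape(pr), "identical")
  peak <- which(ls$density == max(ls$density), arr.ind = TRUE)[1, ]
  expect_equal(ls$s1[peak[1]], 1.5, tolerance = 0.01)
  expect_equal(ls$s2[peak[2]], -2, tolerance = 0.01)

  # uniform disc: density beyond 3 bandwidths of the disc < 1% of peak
  set.seed(43)
  n <- 2000
  r <- 3 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  pr2 <- data.frame(S1 = r * cos(th), S2 = r * sin(th))
  ls2 <- estimate_landscape(pr2)
  hmax <- max(ls2$bandwidth)
  ring <- cbind((3 + 3.01 * hmax) * cos(seq(0, 2 * pi, length.out = 36)),
                (3 + 3.01 * hmax) * sin(seq(0, 2 * pi, length.out = 36)))
  outside <- landscape_density_at(ls2, ring)
  expect_lt(max(outside), 0.01 * max(ls2$density))
})

test_that("mode arrows reshape eigenvectors with unit norm and locality", {
  st <- generate_structure(fast_spec())
  gen <- generate_ensemble(st, "dH2A/H2B", fast_spec(drift = 0))
  al <- align_ensemble(gen$ensemble, "histone_core_only")
  suppressWarnings(md <- compute_modes(al))
  arrows <- export_mode_arrows(md, 1)
  expect_equal(sum(arrows$norm^2), 1, tolerance = 1e-8)

  # >80% of the mode norm lives on the scheduled arm beads
  key <- paste(arrows$chain, arrows$residue_index)
  armk <- paste(gen$truth$arm_labels$chain, gen$truth$arm_labels$residue_index)
  expect_gt(sum(arrows$norm[key %in% armk]^2), 0.8)

  # arrows of modes 1 and 2 are orthogonal as 3N vectors
  a2 <- export_mode_arrows(md, 2)
  dot <- sum(arrows$dx * a2$dx + arrows$dy * a2$dy + arrows$dz * a2$dz)
  expect_equal(dot, 0, tolerance = 1e-8)
})
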
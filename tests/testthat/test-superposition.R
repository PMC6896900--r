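test_that("superposition recovers exact rigid motions", {
  set.seed(2)
  A <- matrix(rnorm(18), 6, 3)
  # identity case
  f0 <- kabsch_superpose(A, A)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(f0$rmsd, 0, tolerance = 1e-12)

  # 90 degrees about z plus translation: recovered to numerical precision
  B <- sweep(A %*% rot_z(90), 2, c(5, 0, 0), "+")
  f <- kabsch_superpose(B, A)
  expect_lt(f$rmsd, 1e-9)
  expect_equal(apply_transform(B, f), A, tolerance = 1e-9)
  # proper rotation
  expect_equal(crossprod(f$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(f$rotation), 1, tolerance = 1e-8)
})

test_that("kabsch fit matches the quaternion-grid oracle on random instances", {
  grid <- quat_rotation_grid(2e5)
  set.seed(7)
  for (i in 1:30) {
    A <- matrix(rnorm(18, sd = 3), 6, 3)
    B <- matrix(rnorm(18, sd = 3), 6, 3)
    k <- kabsch_superpose(A, B)$rmsd
    o <- oracle_min_rmsd(A, B, grid)
    expect_lte(k, o + 1e-3)
    expect_lte(o - k, 0.2)   # grid resolution bound
  }
})

test_that("kabsch agrees with an independent least-squares fitter", {
  set.seed(13)
  A <- matrix(rnorm(30, sd = 4), 10, 3)
  B <- A %*% rot_z(35) + matrix(rnorm(30, sd = 0.5), 10, 3)
  ours <- kabsch_superpose(A, B)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(B)), mobile = as.vector(t(A))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - B)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-8)
})

test_that("structure_rmsd matches a hand-worked Procrustes optimum", {
  # A is a unit cross in the xy plane, B the same cross stretched to
  # half-axes 2 and 3; the cross-covariance is diagonal with positive
  # entries so the optimal rotation is the identity and
  # rmsd^2 = ((2-1)^2 * 2 + (3-1)^2 * 2) / 4 = 2.5.
  A <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  B <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 3, 0), c(0, -3, 0))
  expect_equal(structure_rmsd(A, B), sqrt(2.5), tolerance = 1e-10)
  expect_equal(structure_rmsd(A, A), 0, tolerance = 1e-12)
})

test_that("rmsd is symmetric and rigid-invariant", {
  set.seed(21)
  A <- matrix(rnorm(24, sd = 5), 8, 3)
  B <- matrix(rnorm(24, sd = 5), 8, 3)
  r1 <- structure_rmsd(A, B)
  r2 <- structure_rmsd(B, A)
  expect_equal(r1, r2, tolerance = 1e-8)
  Arot <- sweep(A %*% rot_z(123), 2, c(3, -7, 2), "+")
  expect_equal(structure_rmsd(Arot, B), r1, tolerance = 1e-8)

  # separate fit and measure masks
  fitted_on_half <- structure_rmsd(A, B, fit_mask = 1:4, measure_mask = 5:8)
  expect_gte(fitted_on_half, 0)
})

test_that("fitting is unweighted: mask duplication equals row duplication", {
  set.seed(31)
  A <- matrix(rnorm(15), 5, 3)
  B <- matrix(rnorm(15), 5, 3)
  dup_mask <- kabsch_superpose(A, B, mask = c(1:5, 3L))
  dup_rows <- kabsch_superpose(A[c(1:5, 3), ], B[c(1:5, 3), ])
  expect_equal(dup_mask$rotation, dup_rows$rotation, tolerance = 1e-10)
  expect_equal(dup_mask$rmsd, dup_rows$rmsd, tolerance = 1e-10)
})

test_that("degenerate geometries raise instead of fitting improperly", {
  line <- cbind(1:5, 0, 0) * 1.0
  expect_error(kabsch_superpose(line, line), "collinear")
  two <- matrix(rnorm(6), 2, 3)
  expect_error(kabsch_superpose(two, two), ">= 3 atoms")
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 5, 3)),
               "length mismatch")
})

test_that("align_ensemble removes rigid motion and stores transforms", {
  st <- generate_structure(fast_spec())
  spec0 <- fast_spec(noise_sigma = 0, wobble = list(enabled = TRUE))
  gen <- generate_ensemble(st, "canonical", spec0)
  ens <- gen$ensemble

  al <- align_ensemble(ens, "whole_complex")
  ref <- nucdyn:::frame_coords(ens$trials[[1]], 1L)
  for (f in c(1, 30, 77)) {
    fr <- nucdyn:::frame_coords(al$trials[[1]], f)
    expect_lt(max(abs(fr - ref)), 1e-6)
  }
  # stored per-frame transform reproduces the aligned frame from the raw one
  f <- 42L
  raw <- nucdyn:::frame_coords(ens$trials[[1]], f)
  tf <- al$transforms[[1]][[f]]
  expect_equal(apply_transform(raw, tf),
               nucdyn:::frame_coords(al$trials[[1]], f), tolerance = 1e-6)

  # static ensemble is unchanged by either convention
  stat <- manual_ensemble(st$topology, list(st$coords, st$coords))
  al2 <- align_ensemble(stat, "histone_core_only")
  expect_equal(al2$trials[[1]]$coords, stat$trials[[1]]$coords,
               tolerance = 1e-8)
})

test_that("core-only alignment leaves DNA deformation intact", {
  st <- generate_structure(fast_spec())
  spec <- fast_spec(noise_sigma = 0, wobble = list(enabled = TRUE), drift = 0)
  gen <- generate_ensemble(st, "dH2A/H2B", spec)
  al <- align_ensemble(gen$ensemble, "histone_core_only")
  topo <- al$topology
  core <- make_selection(topo, label = "align_histone_core_only")
  ref <- nucdyn:::frame_coords(gen$ensemble$trials[[1]], 1L)
  # per-frame oracle: histone cores coincide with reference, arm beads move
  arm <- gen$truth$arm_atom_idx
  moved <- FALSE
  for (f in c(10, 25, 40)) {
    fr <- nucdyn:::frame_coords(al$trials[[1]], f)
    oracle <- kabsch_superpose(nucdyn:::frame_coords(gen$ensemble$trials[[1]], f),
                               ref, core)
    expect_lt(oracle$rmsd, 1e-6)
    expect_lt(max(abs(fr[core$indices, ] - ref[core$indices, ])), 1e-5)
    if (max(abs(fr[arm, ] - ref[arm, ])) > 0.5) moved <- TRUE
  }
  expect_true(moved)
})
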
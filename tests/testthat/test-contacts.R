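# two-atom fixtures: one C1' bead (chain I) and one CA bead (chain C)
pair_topology <- function() {
  atoms <- data.frame(atom_id = 1:2, atom_name = c("C1'", "CA"),
                      element = "C", chain_id = c("I", "C"),
                      residue_index = c(0L, 50L),
                      residue_name = c("DA", "ALA"), stringsAsFactors = FALSE)
  complex_topology(atoms, default_chain_map())
}

pair_ensemble <- function(distances) {
  frames <- lapply(distances, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  manual_ensemble(pair_topology(), frames)
}

test_that("cutoff boundary is strict and frequencies are exact ratios", {
  ens <- pair_ensemble(rep(9.9, 5))
  expect_equal(as.numeric(contact_frequency(ens, window = analysis_window(0))), 1)
  ens <- pair_ensemble(rep(10.1, 5))
  expect_equal(as.numeric(contact_frequency(ens, window = analysis_window(0))), 0)
  # exactly at the cutoff: "less than" means no contact
  ens <- pair_ensemble(rep(10.0, 5))
  expect_equal(as.numeric(contact_frequency(ens, window = analysis_window(0))), 0)

  # deterministic schedule: below cutoff in exactly 40 of 100 frames
  sched <- ifelse(seq_len(100) %% 5 < 2, 8, 12)
  stopifnot(sum(sched < 10) == 40)
  ens <- pair_ensemble(sched)
  expect_equal(as.numeric(contact_frequency(ens, window = analysis_window(0))),
               0.40)

  expect_error(contact_frequency(pair_ensemble(5), cutoff = -1), "positive")
})

test_that("frequencies are rigid-invariant and cutoff-monotone", {
  st <- generate_structure(fast_spec())
  gen <- generate_ensemble(st, "canonical")
  ens <- gen$ensemble
  f1 <- contact_frequency(ens)

  R <- rot_z(222); tvec <- c(-30, 12, 100)
  trials2 <- lapply(ens$trials, function(tr) {
    for (f in seq_len(dim(tr$coords)[1]))
      tr$coords[f, , ] <- sweep(tr$coords[f, , ] %*% R, 2, tvec, "+")
    tr
  })
  f2 <- contact_frequency(trajectory_ensemble(ens$topology, trials2, 10))
  expect_equal(unclass(f1)[, ], unclass(f2)[, ], tolerance = 1e-12)

  f_small <- contact_frequency(ens, cutoff = 8)
  expect_true(all(unclass(f1)[, ] >= unclass(f_small)[, ]))
})

test_that("pooled frequency is the frame-weighted mean of per-trial counts", {
  topo <- pair_topology()
  # trial 1: 30 of 100 frames in contact; trial 2: 50 of 100
  d1 <- c(rep(5, 30), rep(20, 70))
  d2 <- c(rep(5, 50), rep(20, 50))
  mk <- function(d) {
    coords <- array(0, dim = c(length(d), 2, 3))
    for (f in seq_along(d)) coords[f, , ] <- rbind(c(0, 0, 0), c(d[f], 0, 0))
    coords
  }
  ens <- trajectory_ensemble(topo, list(mk(d1), mk(d2)), 10)
  f <- contact_frequency(ens, window = analysis_window(0))
  expect_equal(as.numeric(f), (30 + 50) / 200)
})

test_that("spatial-partition engine is bit-equivalent to the all-pairs loop", {
  set.seed(53)
  for (rep in 1:40) {
    P <- matrix(runif(3 * 25, -35, 35), ncol = 3)
    Q <- matrix(runif(3 * 60, -35, 35), ncol = 3)
    expect_identical(nucdyn:::contact_hits_cells(P, Q, 10),
                     nucdyn:::contact_hits_all_pairs(P, Q, 10))
  }
})

test_that("tail submatrix restriction follows set algebra", {
  st <- generate_structure(fast_spec())
  gen <- generate_ensemble(st, "canonical")
  f <- contact_frequency(gen$ensemble)

  # H2A C-terminal tail: 30 columns (residues 99..128 of chain C)
  sub <- tail_contact_submatrix(f, cols = data.frame(chain = "C",
                                                     from = 99, to = 128))
  expect_equal(ncol(sub), 30)
  expect_equal(nrow(sub), nrow(f))

  # restriction of a restriction equals the intersected restriction
  a <- tail_contact_submatrix(f, cols = data.frame(chain = "C",
                                                   from = 90, to = 128))
  ab <- tail_contact_submatrix(a, cols = data.frame(chain = "C",
                                                    from = 99, to = 140))
  direct <- tail_contact_submatrix(f, cols = data.frame(chain = "C",
                                                        from = 99, to = 128))
  expect_equal(unclass(ab)[, ], unclass(direct)[, ])

  # restriction to an absent region errors
  gen2 <- generate_ensemble(st, "dH3/H4")
  f2 <- contact_frequency(gen2$ensemble)
  expect_error(tail_contact_submatrix(f2, cols = data.frame(chain = "A",
                                                            from = 1, to = 44)),
               "empty restriction")
})

test_that("matrix differences are exact and label-aware", {
  st <- generate_structure(fast_spec())
  gen <- generate_ensemble(st, "canonical")
  f <- contact_frequency(gen$ensemble)
  d0 <- matrix_difference(f, f)
  expect_true(all(unclass(d0)[, ] == 0))

  # hand-built 2x2 case
  mk2 <- function(vals) {
    m <- matrix(vals, 2, 2,
                dimnames = list(c("I:0", "I:1"), c("C:50", "C:51")))
    structure(m, class = c("ContactFrequencyMatrix", "matrix"),
              cutoff = 10, n_frames = 10,
              row_labels = data.frame(chain = "I", residue_index = 0:1),
              col_labels = data.frame(chain = "C", residue_index = 50:51))
  }
  a <- mk2(c(1, 0.5, 0.2, 0)); b <- mk2(c(0.4, 0.5, 0.1, 0.3))
  d <- matrix_difference(a, b)
  expect_equal(unclass(d)[, ], matrix(c(0.6, 0, 0.1, -0.3), 2, 2,
               dimnames = dimnames(a)))

  expect_error(matrix_difference(a, structure(matrix(0, 1, 1,
    dimnames = list("J:5", "D:9")), class = class(a),
    row_labels = data.frame(chain = "J", residue_index = 5),
    col_labels = data.frame(chain = "D", residue_index = 9))),
    "no row/column labels")
})
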
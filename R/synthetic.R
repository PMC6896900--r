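# Deterministic coarse-grained emulator of nucleosome trajectories.
#
# One bead per residue (C1' for nucleotides, CA for amino acids) on a
# left-handed DNA superhelix wrapped around eight compact histone clusters
# with explicit tail beads. Frames are reference + localized sinusoidal
# "breathing" of the DNA arm next to a deleted dimer + optional slow drift
# of that arm (H2A/H2B deletions), + optional repositioning of the adjacent
# H2A C-terminal tail into the vacated patch (H3/H4 deletions), + isotropic
# Gaussian thermal noise, + optional rigid wobble to exercise alignment.
# Everything is seeded per (seed, trial) and bitwise reproducible.

#' Specification for the synthetic nucleosome generator
#'
#' Defaults emulate the canonical nucleosome geometry (147 bp on a
#' left-handed superhelix of radius 41.9 A, pitch 25.9 A, 1.65 turns;
#' histone bead counts matching the core/tail region table) and a sampling
#' scheme of 10 trials at 10 ps intervals.
#'
#' @param dna_bp base pairs (beads per strand).
#' @param radius,pitch,turns superhelix geometry (A, A, turns).
#' @param breathing list: `extent_bp` arm beads per strand, `amplitude`
#'   peak displacement (A), `period_frames`, `normalize` ("bead": each arm
#'   bead moves `amplitude`; "collective": the whole 3N mode vector has unit
#'   norm and peak collective displacement `amplitude`), `invasion_damping`
#'   amplitude multiplier when the H2A C-tail fills the vacated site.
#' @param drift slow outward displacement (A per arm bead) of the freed arm
#'   for H2A/H2B deletions, ramping over the first half of each trial.
#' @param noise_sigma per-coordinate Gaussian noise sd (A).
#' @param tail_invasion move the adjacent H2A C-terminal beads into the
#'   vacated H3/H4 patch (only affects H3/H4-deleted variants).
#' @param wobble list: `enabled`, `angle_deg`, `shift`, `period_frames` -
#'   slow rigid rotation about z plus translation applied to every bead.
#' @param n_trials,n_frames,sampling_interval trials, frames per trial, ps.
#' @param seed integer master seed.
#' @return SyntheticSpec list.
#' @export
synthetic_spec <- function(dna_bp = 147,
                           radius = 41.9, pitch = 25.9, turns = 1.65,
                           breathing = list(),
                           drift = 15,
                           noise_sigma = 0.5,
                           tail_invasion = TRUE,
                           wobble = list(),
                           n_trials = 10, n_frames = 1000,
                           sampling_interval = 10,
                           seed = 1) {
  br <- utils::modifyList(list(extent_bp = 10, amplitude = 6,
                               period_frames = 100, normalize = "bead",
                               invasion_damping = 0.25), breathing)
  wb <- utils::modifyList(list(enabled = FALSE, angle_deg = 5, shift = 3,
                               period_frames = 200), wobble)
  stopifnot(dna_bp >= 4, radius > 0, pitch > 0,
            br$amplitude >= 0, noise_sigma >= 0,
            n_trials >= 1, n_frames >= 1)
  if (turns <= 0) stop("degenerate geometry: superhelix needs turns > 0")
  spec <- list(dna_bp = dna_bp, radius = radius, pitch = pitch, turns = turns,
               breathing = br, drift = drift, noise_sigma = noise_sigma,
               tail_invasion = tail_invasion, wobble = wb,
               n_trials = n_trials, n_frames = n_frames,
               sampling_interval = sampling_interval, seed = seed)
  class(spec) <- "SyntheticSpec"
  spec
}

# bp index range (strand-I numbering, -half..half) each dimer organizes
dimer_patches <- function(half) {
  q <- floor(half * 0.6)
  list("H2A'/H2B'" = c(-half, -q - 1),
       "H3'/H4'"   = c(-q, -1),
       "H3/H4"     = c(0, q),
       "H2A/H2B"   = c(q + 1, half))
}

fib_sphere <- function(n, r) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  r * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a synthetic nucleosome-like structure
#'
#' DNA C1' beads lie on a left-handed superhelix (strand J offset axially
#' from its paired strand-I bead, residue j of J paired with residue -j of
#' I); each histone chain is a compact bead cluster at its dimer position
#' with tail beads extending axially away from the DNA.
#'
#' @param spec SyntheticSpec.
#' @return list(topology, coords, truth) where `truth` carries the arm-bead
#'   labels, injected-mode vectors, per-bead expected RMSF and invasion
#'   targets used as test oracles.
#' @export
generate_structure <- function(spec = synthetic_spec()) {
  half <- (spec$dna_bp - 1) %/% 2
  bp <- seq(-half, half)
  s <- (bp + half) / (spec$dna_bp - 1)
  theta <- 2 * pi * spec$turns * s
  z <- spec$pitch * spec$turns * s
  z <- z - mean(z)
  # left-handed: clockwise when viewed down +z
  pos_i <- cbind(spec$radius * cos(-theta), spec$radius * sin(-theta), z)
  normals <- cbind(cos(-theta), sin(-theta), 0)
  pos_j <- pos_i + matrix(rep(c(0, 0, 10), each = nrow(pos_i)), ncol = 3)

  atoms <- list(); coords <- list(); id <- 0L
  add_atom <- function(name, el, chain, res, resname, xyz) {
    id <<- id + 1L
    atoms[[id]] <<- data.frame(atom_id = id, atom_name = name, element = el,
                               chain_id = chain, residue_index = res,
                               residue_name = resname, stringsAsFactors = FALSE)
    coords[[id]] <<- xyz
  }
  rt <- default_region_table()
  chain_map <- default_chain_map()
  patches <- dimer_patches(half)
  role_of <- list(A = "H3", B = "H4", C = "H2A", D = "H2B",
                  E = "H3'", F = "H4'", G = "H2A'", H = "H2B'")
  dimer_of <- c(A = "H3/H4", B = "H3/H4", C = "H2A/H2B", D = "H2A/H2B",
                E = "H3'/H4'", F = "H3'/H4'", G = "H2A'/H2B'", H = "H2A'/H2B'")
  for (ch in names(role_of)) {
    role <- role_of[[ch]]
    sub <- rt[rt$role == role, ]
    n_res <- max(sub$to)
    core <- sub[sub$region == "core", ]
    patch <- patches[[dimer_of[[ch]]]]
    pb <- bp >= patch[1] & bp <= patch[2]
    ang <- atan2(mean(pos_i[pb, 2]), mean(pos_i[pb, 1]))
    # two chains of a dimer sit side by side, staggered axially
    first_of_dimer <- ch %in% c("A", "C", "E", "G")
    ang <- ang + if (first_of_dimer) -0.3 else 0.3
    zoff <- if (first_of_dimer) -5 else 5
    center <- c(30 * cos(ang), 30 * sin(ang), mean(pos_i[pb, 3]) + zoff)
    n_core <- core$to - core$from + 1
    cluster <- sweep(fib_sphere(n_core, 6), 2, center, "+")
    ci <- 0L
    # N-tails run axially away from the chain's own DNA gyre; the H2A
    # C-tail runs radially inward through the empty axial channel
    zsign <- if (ch %in% c("A", "B", "C", "D")) 2 else -2
    tail_n_dir <- vec_unit(c(0.2 * cos(ang), 0.2 * sin(ang), zsign))
    # C-tail tilts into the axial channel, clear of the DNA shell
    tail_c_dir <- vec_unit(c(-0.4 * cos(ang), -0.4 * sin(ang), zsign / 2))
    for (res in seq_len(n_res)) {
      region <- classify_residue(role, res, rt)
      if (region == "core") {
        ci <- ci + 1L
        xyz <- cluster[ci, ]
      } else if (region == "tail_n") {
        k <- core$from - res              # distance from core start
        xyz <- center + tail_n_dir * (8 + 3.8 * k)
      } else {                            # tail_c (H2A only)
        k <- res - core$to
        xyz <- center + tail_c_dir * (8 + 3.8 * k)
      }
      add_atom("CA", "C", ch, res, "ALA", xyz)
    }
  }
  for (r in seq_along(bp)) add_atom("C1'", "C", "I", bp[r], "DA", pos_i[r, ])
  for (r in seq_along(bp)) add_atom("C1'", "C", "J", bp[r], "DT",
                                    pos_j[nrow(pos_j) + 1L - r, ])
  atoms <- do.call(rbind, atoms)
  xyz <- do.call(rbind, coords)
  dimnames(xyz) <- NULL
  dm <- as.matrix(stats::dist(xyz))
  diag(dm) <- Inf
  dmin <- min(dm)
  if (dmin < 1) {
    w <- which(dm == dmin, arr.ind = TRUE)[1, ]
    stop("degenerate geometry: beads closer than 1 A (",
         signif(dmin, 3), " A between ",
         atoms$chain_id[w[1]], ":", atoms$residue_index[w[1]], " and ",
         atoms$chain_id[w[2]], ":", atoms$residue_index[w[2]], ")")
  }
  topo <- complex_topology(atoms, chain_map)
  truth <- list(bp = bp, half = half, patches = patches,
                strand_i_pos = pos_i, normals = normals)
  list(topology = topo, coords = xyz, truth = truth, spec = spec)
}

# atom indices (canonical topology) and outward normals of the breathing arm
arm_beads <- function(structure, variant) {
  spec <- structure$spec
  tr <- structure$truth
  ext <- spec$breathing$extent_bp
  half <- tr$half
  patch_bp <- switch(variant,
    "canonical"  = integer(0),
    "dH2A/H2B"   = seq(half - ext + 1, half),
    "dH2A'/H2B'" = seq(-half, -half + ext - 1),
    "dH3/H4"     = {
      p <- tr$patches[["H3/H4"]]
      mid <- round(mean(p)); seq(mid - (ext - 1) %/% 2, length.out = ext)
    },
    "dH3'/H4'"   = {
      p <- tr$patches[["H3'/H4'"]]
      mid <- round(mean(p)); seq(mid - (ext - 1) %/% 2, length.out = ext)
    })
  a <- structure$topology$atoms
  idx_i <- which(a$chain_id == "I" & a$residue_index %in% patch_bp)
  idx_j <- which(a$chain_id == "J" & a$residue_index %in% (-patch_bp))
  idx <- c(idx_i, idx_j)
  nrm <- matrix(0, length(idx), 3)
  for (k in seq_along(idx)) {
    res <- a$residue_index[idx[k]]
    i_bp <- if (a$chain_id[idx[k]] == "I") res else -res
    nrm[k, ] <- tr$normals[match(i_bp, tr$bp), ]
  }
  list(bp = patch_bp, atom_idx = idx, normals = nrm)
}

#' Generate a synthetic trajectory ensemble for a model variant
#'
#' Frames are the reference structure plus: a sinusoidal breathing
#' deformation of the DNA arm adjacent to the deleted dimer (amplitude
#' damped by `invasion_damping` for H3/H4 deletions with tail invasion on;
#' zero for the canonical variant), a slow outward drift of that arm for
#' H2A/H2B deletions (ramping over the first half, so the latter half
#' fluctuates about a displaced centre), repositioning of the adjacent H2A
#' C-terminal beads into the vacated patch for H3/H4 deletions, isotropic
#' Gaussian noise, and an optional rigid wobble. Deleted chains are removed.
#'
#' @param structure result of [generate_structure()] (canonical).
#' @param variant one of [model_variants()].
#' @param spec optional SyntheticSpec overriding the structure's.
#' @return list(ensemble = TrajectoryEnsemble, truth = ground-truth list).
#' @export
generate_ensemble <- function(structure, variant = "canonical", spec = NULL) {
  if (is.null(spec)) spec <- structure$spec
  variant <- match.arg(variant, VARIANTS)
  red <- build_variant(structure$topology, variant, structure$coords)
  topo <- red$topology
  ref <- red$coords
  n <- nrow(ref)
  arm <- arm_beads(structure, variant)
  # map canonical atom indices to reduced topology
  del_roles <- variant_deleted_roles(variant)
  del_chains <- structure$topology$chain_ids[
    structure$topology$chain_roles %in% del_roles]
  keep <- !(structure$topology$atoms$chain_id %in% del_chains)
  newpos <- cumsum(keep)
  arm_idx <- newpos[arm$atom_idx]            # DNA survives every deletion

  is_h2ab_del <- variant %in% c("dH2A/H2B", "dH2A'/H2B'")
  is_h34_del <- variant %in% c("dH3/H4", "dH3'/H4'")
  amp <- spec$breathing$amplitude
  if (variant == "canonical") amp <- 0
  if (is_h34_del && spec$tail_invasion) amp <- amp * spec$breathing$invasion_damping
  n_arm <- length(arm_idx)
  per_bead_amp <- if (n_arm == 0) 0
    else if (spec$breathing$normalize == "collective") amp / sqrt(n_arm)
    else amp

  # unit injected-mode vector over the reduced topology's C1' ordering
  dna_mask <- make_selection(topo, label = "dna_c1p")
  mode3N <- numeric(3 * length(dna_mask$indices))
  pos_in_mask <- match(arm_idx, dna_mask$indices)
  for (k in seq_len(n_arm)) {
    j <- 3 * (pos_in_mask[k] - 1)
    mode3N[j + 1:3] <- arm$normals[k, ]
  }
  mode_unit <- if (n_arm) mode3N / sqrt(sum(mode3N^2)) else mode3N

  invasion <- NULL
  if (is_h34_del && spec$tail_invasion) {
    invader_role <- if (variant == "dH3/H4") "H2A" else "H2A'"
    inv_chain <- topo$chain_ids[topo$chain_roles == invader_role]
    rt <- default_region_table()
    tc <- rt[rt$role == invader_role & rt$region == "tail_c", ]
    a <- topo$atoms
    tail_idx <- which(a$chain_id == inv_chain &
                      a$residue_index >= tc$from & a$residue_index <= tc$to)
    # vacated patch DNA beads (strand I) and inward-offset targets
    patch <- structure$truth$patches[[sub("^d", "", variant)]]
    patch_bp <- seq(patch[1], patch[2])
    at_all <- topo$atoms
    patch_dna <- which(at_all$chain_id == "I" & at_all$residue_index %in% patch_bp)
    tgt_src <- patch_dna[1 + (seq_along(tail_idx) - 1) %% length(patch_dna)]
    targets <- ref[tgt_src, , drop = FALSE]
    for (k in seq_along(tail_idx)) {
      res <- at_all$residue_index[tgt_src[k]]
      nrm <- structure$truth$normals[match(res, structure$truth$bp), ]
      targets[k, ] <- targets[k, ] - 6 * nrm
    }
    invasion <- list(chain = inv_chain, tail_idx = tail_idx,
                     targets = targets, patch_bp = patch_bp,
                     patch_dna_idx = patch_dna)
  }

  nf <- spec$n_frames
  period <- spec$breathing$period_frames
  trials <- vector("list", spec$n_trials)
  for (tr in seq_len(spec$n_trials)) {
    set.seed((spec$seed %% 100000L) * 10007L + tr)
    phase <- stats::runif(1, 0, 2 * pi)
    coords <- array(0, dim = c(nf, n, 3))
    for (f in seq_len(nf)) {
      x <- ref
      ramp <- min(1, f / (nf / 2))
      if (n_arm) {
        b <- per_bead_amp * sin(2 * pi * f / period + phase)
        x[arm_idx, ] <- x[arm_idx, ] + b * arm$normals
        if (is_h2ab_del && spec$drift > 0)
          x[arm_idx, ] <- x[arm_idx, ] + spec$drift * ramp * arm$normals
      }
      if (!is.null(invasion)) {
        x[invasion$tail_idx, ] <- (1 - ramp) * x[invasion$tail_idx, ] +
          ramp * invasion$targets
      }
      if (spec$wobble$enabled) {
        ang <- spec$wobble$angle_deg * pi / 180 *
          sin(2 * pi * f / spec$wobble$period_frames)
        R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
        x <- x %*% R
        x[, 1] <- x[, 1] + spec$wobble$shift *
          sin(2 * pi * f / spec$wobble$period_frames)
      }
      if (spec$noise_sigma > 0)
        x <- x + matrix(stats::rnorm(3 * n, 0, spec$noise_sigma), n, 3)
      coords[f, , ] <- x
    }
    trials[[tr]] <- list(times = seq_len(nf) * spec$sampling_interval,
                         coords = coords)
  }
  ensemble <- trajectory_ensemble(topo, trials, spec$sampling_interval)

  expected_rmsf <- rep(sqrt(3) * spec$noise_sigma, length(dna_mask$indices))
  if (n_arm) expected_rmsf[pos_in_mask] <-
    sqrt(3 * spec$noise_sigma^2 + per_bead_amp^2 / 2)
  truth <- list(variant = variant,
                arm_bp = arm$bp, arm_atom_idx = arm_idx,
                arm_labels = label_df(topo, arm_idx),
                mode_unit = mode_unit,
                per_bead_amplitude = per_bead_amp,
                collective_amplitude = if (n_arm) per_bead_amp * sqrt(n_arm) else 0,
                expected_rmsf = expected_rmsf,
                rmsf_labels = label_df(topo, dna_mask$indices),
                invasion = invasion)
  list(ensemble = ensemble, truth = truth)
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits the PDB topology, one plain-text trajectory per trial and a
#' ground-truth TSV, in exactly the formats [read_structure()] and
#' [read_trajectory()] consume.
#'
#' @param dir output directory (created).
#' @param structure from [generate_structure()].
#' @param variant model variant.
#' @param spec optional SyntheticSpec override.
#' @return Invisibly, list of written paths.
#' @export
write_fixture_bundle <- function(dir, structure, variant = "canonical",
                                 spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_ensemble(structure, variant, spec)
  ens <- gen$ensemble
  red <- build_variant(structure$topology, variant, structure$coords)
  pdb <- file.path(dir, "topology.pdb")
  write_structure(red$topology, red$coords, pdb)
  traj <- character(0)
  for (k in seq_along(ens$trials)) {
    p <- file.path(dir, sprintf("trial_%02d.trj", k))
    write_text_trajectory(ens$trials[[k]], p)
    traj <- c(traj, p)
  }
  gt <- file.path(dir, "ground_truth.tsv")
  utils::write.table(
    cbind(gen$truth$rmsf_labels, expected_rmsf = gen$truth$expected_rmsf),
    gt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(topology = pdb, trajectories = traj, ground_truth = gt))
}
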
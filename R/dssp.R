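# Backbone alpha-helix assignment from hydrogen-bond energies, following the
# classical dipole-dipole criterion of Kabsch & Sander: a backbone
# N-H...O=C bond exists when
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  [kcal/mol]
# is below -0.5 kcal/mol. Amide hydrogens are always reconstructed from
# backbone geometry (N-H of length 1.0 A along the bisector opposite
# C(i-1) and CA), so the assignment is independent of force-field H
# placement and works on structures without hydrogens.

HB_Q1Q2F <- 0.084 * 332          # kcal/mol * A, dipole coupling constant
HB_THRESHOLD <- -0.5             # kcal/mol

vec_unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Backbone hydrogen-bond energy (kcal/mol)
#'
#' Electrostatic dipole-dipole energy between an acceptor carbonyl (C, O)
#' and a donor amide (N, H), in the classical formulation; a bond is
#' declared when the energy is below -0.5 kcal/mol.
#'
#' @param c_pos,o_pos acceptor carbonyl C and O positions (length-3, A).
#' @param n_pos,h_pos donor amide N and H positions (length-3, A).
#' @return Energy in kcal/mol (0 in the infinite-separation limit).
#' @export
backbone_hbond_energy <- function(c_pos, o_pos, n_pos, h_pos) {
  r_on <- sqrt(sum((o_pos - n_pos)^2))
  r_ch <- sqrt(sum((c_pos - h_pos)^2))
  r_oh <- sqrt(sum((o_pos - h_pos)^2))
  r_cn <- sqrt(sum((c_pos - n_pos)^2))
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(-Inf)  # clashing geometry
  HB_Q1Q2F * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

#' Reconstruct an amide hydrogen position
#'
#' H is placed 1.0 A from N along the bisector opposite the C(i-1)-N-CA
#' angle (the in-plane direction pointing away from both neighbours).
#'
#' @param n_pos,ca_pos backbone N and CA of the residue.
#' @param c_prev_pos carbonyl C of the preceding residue.
#' @return length-3 H position.
#' @export
reconstruct_amide_h <- function(n_pos, ca_pos, c_prev_pos) {
  d <- vec_unit(n_pos - c_prev_pos) + vec_unit(n_pos - ca_pos)
  n_pos + vec_unit(d) * 1.0
}

# Backbone atom indices per residue of one chain: matrix res x {N, CA, C, O}
backbone_index_table <- function(topology, chain_id) {
  a <- topology$atoms
  sel <- which(a$chain_id == chain_id)
  resv <- unique(a$residue_index[sel])
  resv <- resv[order(resv)]
  tab <- matrix(NA_integer_, length(resv), 4,
                dimnames = list(NULL, c("N", "CA", "C", "O")))
  for (nm in c("N", "CA", "C", "O")) {
    idx <- sel[a$atom_name[sel] == nm]
    tab[match(a$residue_index[idx], resv), nm] <- idx
  }
  list(residues = resv, idx = tab)
}

#' Per-residue alpha-helix assignment of one frame
#'
#' A 4-turn starts at residue i when the carbonyl of i hydrogen-bonds the
#' amide of i+4; a minimal alpha-helix spans residues i..i+3 whenever
#' 4-turns start at both i-1 and i, and overlapping minimal helices merge.
#' Residues with incomplete backbones are skipped (never helical); chains
#' shorter than 5 residues are all FALSE.
#'
#' @param coords n x 3 frame coordinates.
#' @param topology ComplexTopology (protein chains need N, CA, C, O atoms).
#' @param chains chain ids to assign (default: all histone chains).
#' @param energy_threshold hydrogen-bond energy cutoff, kcal/mol.
#' @return data.frame (chain, residue_index, helix logical).
#' @export
assign_helix <- function(coords, topology, chains = NULL,
                         energy_threshold = HB_THRESHOLD) {
  if (is.null(chains)) {
    chains <- histone_chains(topology)
    if (!length(chains))
      chains <- topology$chain_ids[vapply(topology$chain_ids, function(ch) {
        any(topology$atoms$chain_id == ch & topology$atoms$atom_name == "CA")
      }, logical(1))]
  }
  out <- list()
  for (ch in chains) {
    bt <- backbone_index_table(topology, ch)
    n <- length(bt$residues)
    helix <- rep(FALSE, n)
    if (n >= 5L) {
      complete <- !apply(is.na(bt$idx), 1, any)
      turn4 <- rep(FALSE, n)
      for (i in seq_len(n - 4L)) {
        j <- i + 4L
        # donor amide of j needs the preceding residue's carbonyl for H
        if (!complete[i] || !complete[j] || !complete[j - 1L]) next
        if (bt$residues[j] - bt$residues[i] != 4L) next  # chain break
        h <- reconstruct_amide_h(coords[bt$idx[j, "N"], ],
                                 coords[bt$idx[j, "CA"], ],
                                 coords[bt$idx[j - 1L, "C"], ])
        e <- backbone_hbond_energy(coords[bt$idx[i, "C"], ],
                                   coords[bt$idx[i, "O"], ],
                                   coords[bt$idx[j, "N"], ], h)
        turn4[i] <- e < energy_threshold
      }
      if (n - 4L >= 2L) for (i in 2:(n - 4L)) {
        if (turn4[i - 1L] && turn4[i]) helix[i:(i + 3L)] <- TRUE
      }
    }
    out[[ch]] <- data.frame(chain = ch, residue_index = bt$residues,
                            helix = helix, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Alpha-helix occupancy over an ensemble window
#'
#' Fraction of pooled window frames (all trials) in which each residue is
#' assigned alpha-helical. With equal frame counts per trial, pooling before
#' or after the per-trial ratio coincide; frames are pooled.
#'
#' @param ensemble TrajectoryEnsemble (raw or aligned; assignment is
#'   rigid-invariant).
#' @param window AnalysisWindow (default latter half).
#' @param chains chain ids (default all histone chains).
#' @return data.frame (chain, residue_index, occupancy).
#' @export
helix_occupancy <- function(ensemble, window = analysis_window(),
                            chains = NULL) {
  widx <- resolve_window(ensemble, window)
  topo <- ensemble$topology
  acc <- NULL
  total <- 0L
  for (k in seq_along(ensemble$trials)) {
    tr <- ensemble$trials[[k]]
    for (f in widx[[k]]) {
      a <- assign_helix(frame_coords(tr, f), topo, chains)
      if (is.null(acc)) {
        acc <- a
        acc$count <- as.integer(a$helix)
        acc$helix <- NULL
      } else {
        acc$count <- acc$count + as.integer(a$helix)
      }
      total <- total + 1L
    }
  }
  if (total == 0L) stop("empty analysis window")
  data.frame(chain = acc$chain, residue_index = acc$residue_index,
             occupancy = acc$count / total, stringsAsFactors = FALSE)
}

# --- ideal-geometry peptide construction (test fixture and demo input) ----

# Place atom d from a-b-c by bond length, bond angle (b-c-d) and dihedral
# (a-b-c-d), standard internal-coordinate (NeRF) construction.
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  th <- angle_deg * pi / 180
  ph <- dihedral_deg * pi / 180
  bc <- vec_unit(c - b)
  nrm <- vec_unit(vec_cross(b - a, bc))
  m <- vec_cross(nrm, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), -bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * nrm
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vec_cross(b1, b2); n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, vec_unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Build an ideal poly-alanine backbone from phi/psi angles
#'
#' Constructs an N-CA-C-O backbone with standard bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329, C-O 1.231 A; omega fixed at 180
#' degrees). `phi = -57, psi = -47` gives an ideal alpha helix;
#' `phi = psi = 180` a fully extended chain.
#'
#' @param n_res number of residues.
#' @param phi,psi backbone dihedrals in degrees (scalar or per-residue).
#' @param chain_id chain identifier.
#' @return list(topology = ComplexTopology, coords = n x 3 matrix).
#' @export
build_peptide <- function(n_res, phi = -57, psi = -47, chain_id = "A") {
  stopifnot(n_res >= 2)
  phi <- rep(phi, length.out = n_res)
  psi <- rep(psi, length.out = n_res)
  pos <- list()
  # residue 1 seed
  N1 <- c(0, 0, 0)
  CA1 <- c(1.458, 0, 0)
  th <- 111.2 * pi / 180
  C1 <- CA1 + 1.525 * c(-cos(th), sin(th), 0)
  pos[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n_res - 1L)) {
    p <- pos[[i]]
    Nn <- place_atom(p$N, p$CA, p$C, 1.329, 116.2, psi[i])
    CAn <- place_atom(p$CA, p$C, Nn, 1.458, 121.7, 180)      # omega
    Cn <- place_atom(p$C, Nn, CAn, 1.525, 111.2, phi[i + 1])
    pos[[i + 1L]] <- list(N = Nn, CA = CAn, C = Cn)
  }
  # carbonyl O: in the peptide plane, anti to the next amide N
  for (i in seq_len(n_res)) {
    p <- pos[[i]]
    pos[[i]]$O <- place_atom(p$N, p$CA, p$C, 1.231, 120.8, psi[i] + 180)
  }
  atoms <- list(); coords <- list(); id <- 0L
  for (i in seq_len(n_res)) {
    for (nm in c("N", "CA", "C", "O")) {
      id <- id + 1L
      atoms[[id]] <- data.frame(atom_id = id, atom_name = nm,
                                element = substr(nm, 1, 1), chain_id = chain_id,
                                residue_index = i, residue_name = "ALA",
                                stringsAsFactors = FALSE)
      coords[[id]] <- pos[[i]][[nm]]
    }
  }
  atoms <- do.call(rbind, atoms)
  cm <- stats::setNames("H3", chain_id)   # treat as a histone-like chain
  list(topology = complex_topology(atoms, cm),
       coords = do.call(rbind, coords))
}
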
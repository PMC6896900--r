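#' Read a structure file into a topology plus reference coordinates
#'
#' PDB records are parsed with bio3d; alternate locations are resolved to the
#' highest occupancy, ties broken alphabetically by altloc id. Atom order of
#' the file is preserved. Hydrogens, water and ions are retained in the
#' topology (analysis masks exclude them).
#'
#' @param path PDB file path.
#' @param chain_map named chain-id -> role map; chains absent from the map
#'   (solvent, ions) are kept and given role "other".
#' @return list(topology = ComplexTopology, coords = n x 3 matrix, Angstrom).
#' @export
read_structure <- function(path, chain_map = default_chain_map()) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (file.size(path) == 0L) stop("structure format error: empty file ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("structure format error in ", path,
                                           ": ", conditionMessage(e)))
  at <- pdb$atom
  # altloc resolution: per (chain, residue, atom name), keep highest occupancy,
  # ties -> alphabetically first altloc id
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  dupkeys <- unique(key[duplicated(key)])
  for (k in dupkeys) {
    rows <- which(key == k)
    if (length(unique(alt[rows])) != length(rows))
      stop("ambiguous duplicate atom (same altloc) in residue ",
           at$resno[rows[1]], " chain ", at$chain[rows[1]])
    ord <- order(-occ[rows], alt[rows])
    keep[rows[-ord[1]]] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  el <- trimws(at$elesy)
  noel <- is.na(el) | el == ""
  if (any(noel)) el[noel] <- guess_element(at$elety[noel])
  chains <- unique(at$chain)
  cm <- chain_map
  extra <- setdiff(chains, names(cm))
  if (length(extra)) {
    add <- stats::setNames(rep("other", length(extra)), extra)
    cm <- c(cm, add)
  }
  atoms <- data.frame(
    atom_id = at$eleno,
    atom_name = trimws(at$elety),
    element = el,
    chain_id = at$chain,
    residue_index = at$resno,
    residue_name = trimws(at$resid),
    stringsAsFactors = FALSE)
  coords <- cbind(at$x, at$y, at$z)
  if (any(!is.finite(coords))) stop("non-finite coordinates in ", path)
  colnames(coords) <- c("x", "y", "z")
  list(topology = complex_topology(atoms, cm), coords = coords)
}

guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", atom_name))
  first <- toupper(substr(nm, 1, 1))
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, toupper(nm))
}

#' Write a topology + coordinates as a PDB file
#'
#' @param topology ComplexTopology.
#' @param coords n x 3 matrix, Angstrom.
#' @param path output path.
#' @export
write_structure <- function(topology, coords, path) {
  a <- topology$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords)),
                   type = "ATOM",
                   eleno = a$atom_id,
                   elety = a$atom_name,
                   resid = a$residue_name,
                   chain = a$chain_id,
                   resno = a$residue_index,
                   elesy = a$element)
  invisible(path)
}

#' Construct a TrajectoryEnsemble
#'
#' A trajectory ensemble is one topology plus one or more trials, each a
#' frames x atoms x 3 coordinate array (Angstrom) with strictly increasing,
#' uniformly spaced frame times (ps). The first saved frame is at
#' t = sampling_interval, so the "latter half" of a 100 ns run sampled every
#' 10 ps spans exactly frames 5001..10000 (50.01-100 ns).
#'
#' @param topology ComplexTopology.
#' @param trials list of frames x atoms x 3 arrays, or of
#'   list(times=, coords=) pairs.
#' @param sampling_interval ps between frames.
#' @return TrajectoryEnsemble.
#' @export
trajectory_ensemble <- function(topology, trials, sampling_interval = 10) {
  if (!length(trials)) stop("at least one trial is required")
  na <- n_atoms(topology)
  trials <- lapply(trials, function(tr) {
    if (is.array(tr) && length(dim(tr)) == 3L)
      tr <- list(times = seq_len(dim(tr)[1]) * sampling_interval, coords = tr)
    d <- dim(tr$coords)
    if (length(d) != 3L || d[3] != 3L) stop("trial coords must be frames x atoms x 3")
    if (d[2] != na)
      stop("topology mismatch: trial has ", d[2], " atoms, topology has ", na)
    if (d[1] < 1L) stop("trial must have at least one frame")
    if (length(tr$times) != d[1]) stop("frame time count mismatch")
    if (d[1] > 1L) {
      dt <- diff(tr$times)
      if (any(dt <= 0)) stop("frame times must be strictly increasing")
      if (diff(range(dt)) > 1e-6 * max(dt))
        stop("frame times must be uniformly spaced")
    }
    tr
  })
  structure(list(topology = topology, trials = trials,
                 sampling_interval = sampling_interval),
            class = "TrajectoryEnsemble")
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  nf <- vapply(x$trials, function(t) dim(t$coords)[1], 1L)
  cat("TrajectoryEnsemble:", length(x$trials), "trial(s),",
      paste(nf, collapse = "/"), "frames,", n_atoms(x$topology),
      "atoms, dt =", x$sampling_interval, "ps\n")
  invisible(x)
}

n_frames <- function(trial) dim(trial$coords)[1]

frame_coords <- function(trial, f) {
  m <- trial$coords[f, , , drop = FALSE]
  dim(m) <- dim(trial$coords)[2:3]
  m
}

#' Read trajectories into an ensemble
#'
#' One trial per path. `.dcd` files are read as the fixed-header
#' single-precision binary trajectory dialect (coordinates in Angstrom);
#' any other extension is read as the plain-text frame format written by
#' [write_text_trajectory()]: per frame a header line `n_atoms time_ps`
#' followed by one `x y z` line per atom.
#'
#' @param topology ComplexTopology the frames must match.
#' @param paths character vector of trajectory files.
#' @param sampling_interval ps; used for dcd files (which carry no times)
#'   and validated against the text format's times.
#' @return TrajectoryEnsemble.
#' @export
read_trajectory <- function(topology, paths, sampling_interval = 10) {
  if (!length(paths)) stop("at least one trajectory path is required")
  na <- n_atoms(topology)
  trials <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("trajectory file not found: ", p)
    if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      m <- bio3d::read.dcd(p, verbose = FALSE)
      nf <- nrow(m)
      nat <- ncol(m) / 3
      if (nat != na)
        stop("topology mismatch in ", p, ": ", nat, " atoms vs ", na)
      coords <- array(0, dim = c(nf, nat, 3))
      for (f in seq_len(nf)) coords[f, , ] <- matrix(m[f, ], ncol = 3, byrow = TRUE)
      list(times = seq_len(nf) * sampling_interval, coords = coords)
    } else {
      read_text_trial(p, na)
    }
  })
  trajectory_ensemble(topology, trials, sampling_interval)
}

read_text_trial <- function(path, n_atoms_expected) {
  con <- file(path, "r")
  on.exit(close(con))
  times <- numeric(0)
  frames <- list()
  repeat {
    hdr <- readLines(con, n = 1L)
    if (!length(hdr)) break
    if (!nzchar(trimws(hdr))) next
    hv <- scan(text = hdr, quiet = TRUE)
    if (length(hv) != 2L) stop("trajectory format error in ", path,
                               ": bad frame header '", hdr, "'")
    nat <- as.integer(hv[1])
    if (nat != n_atoms_expected)
      stop("topology mismatch in ", path, ": frame has ", nat,
           " atoms, topology has ", n_atoms_expected)
    vals <- scan(con, n = 3L * nat, quiet = TRUE)
    if (length(vals) != 3L * nat)
      stop("trajectory format error in ", path, ": truncated frame")
    frames[[length(frames) + 1L]] <- matrix(vals, ncol = 3, byrow = TRUE)
    times <- c(times, hv[2])
  }
  if (!length(frames)) stop("trajectory format error in ", path, ": no frames")
  coords <- array(0, dim = c(length(frames), n_atoms_expected, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  list(times = times, coords = coords)
}

#' Write one trial in the plain-text frame format
#'
#' @param trial list(times, coords) or frames x atoms x 3 array.
#' @param path output path.
#' @param digits printed precision (round-trip is lossless to this precision).
#' @export
write_text_trajectory <- function(trial, path, digits = 6) {
  if (is.array(trial)) trial <- list(times = seq_len(dim(trial)[1]) * 10,
                                     coords = trial)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(trial$coords)[1]
  na <- dim(trial$coords)[2]
  fmt <- paste0("%.", digits, "f")
  for (f in seq_len(nf)) {
    cat(na, " ", sprintf(fmt, trial$times[f]), "\n", sep = "", file = con)
    m <- trial$coords[f, , ]
    writeLines(paste(sprintf(fmt, m[, 1]), sprintf(fmt, m[, 2]),
                     sprintf(fmt, m[, 3])), con)
  }
  invisible(path)
}

#' Define an analysis window
#'
#' Either a start fraction (frames with time strictly greater than
#' `start_fraction * total_time`; the default 0.5 is the latter half of each
#' trial) or an explicit `[from_ps, to_ps]` time range, inclusive.
#'
#' @param start_fraction fraction of total time to discard from the start.
#' @param from_ps,to_ps explicit time range (ps); overrides start_fraction.
#' @return AnalysisWindow.
#' @export
analysis_window <- function(start_fraction = 0.5, from_ps = NULL, to_ps = NULL) {
  w <- list(start_fraction = start_fraction, from_ps = from_ps, to_ps = to_ps)
  class(w) <- "AnalysisWindow"
  w
}

#' Resolve an analysis window to frame indices per trial
#'
#' For a 100 ns trial sampled every 10 ps (first frame at 10 ps), the default
#' latter-half window resolves to frames 5001..10000 (times 50.01-100 ns).
#'
#' @param ensemble TrajectoryEnsemble.
#' @param window AnalysisWindow.
#' @return list of integer frame-index vectors, one per trial.
#' @export
resolve_window <- function(ensemble, window = analysis_window()) {
  lapply(ensemble$trials, function(tr) {
    t <- tr$times
    if (!is.null(window$from_ps)) {
      idx <- which(t >= window$from_ps & t <= window$to_ps)
    } else {
      total <- t[length(t)]
      idx <- which(t > window$start_fraction * total)
    }
    if (!length(idx)) stop("analysis window resolves to zero frames")
    idx
  })
}
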
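# Fixture builders (all in code; nothing on disk).

# Bead chain topology: one named atom per residue.
bead_topology <- function(n, chain_id = "I", atom_name = "C1'",
                          residues = NULL, role_map = default_chain_map()) {
  if (is.null(residues)) residues <- seq_len(n)
  atoms <- data.frame(atom_id = seq_len(n), atom_name = atom_name,
                      element = "C", chain_id = chain_id,
                      residue_index = residues,
                      residue_name = if (atom_name == "C1'") "DA" else "ALA",
                      stringsAsFactors = FALSE)
  complex_topology(atoms, role_map)
}

# Ensemble from an explicit list of n x 3 frames.
manual_ensemble <- function(topology, frames, dt = 10, times = NULL) {
  nf <- length(frames)
  na <- nrow(frames[[1]])
  coords <- array(0, dim = c(nf, na, 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  if (is.null(times)) times <- seq_len(nf) * dt
  trajectory_ensemble(topology, list(list(times = times, coords = coords)), dt)
}

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          occ = 1, alt = " ", element = "C") {
  namef <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, namef, alt, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0, element)
}

write_toy_pdb <- function(path, n = 10, chain = "A") {
  set.seed(99)
  lines <- character(0)
  for (i in seq_len(n)) {
    lines <- c(lines, pdb_atom_line(i, c("N", "CA", "C", "O", "CB")[1 + (i - 1) %% 5],
                                    "ALA", chain, 1 + (i - 1) %/% 5,
                                    round(runif(3, -10, 10), 3)))
  }
  writeLines(c(lines, "END"), path)
  path
}

# small synthetic spec for fast end-to-end tests
fast_spec <- function(...) {
  synthetic_spec(n_trials = 2, n_frames = 120,
                 breathing = list(period_frames = 30), seed = 11, ...)
}
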
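#' Nucleotide-amino-acid contact-frequency matrix
#'
#' A nucleotide and an amino acid are in contact in a frame when the
#' Euclidean distance between the nucleotide's C1' and the residue's CA is
#' strictly less than `cutoff` (a pair at exactly the cutoff is not a
#' contact). The frequency is the fraction of pooled window frames (all
#' trials) in which the pair was in contact. Raw, unaligned coordinates are
#' used; distances are invariant to rigid motion.
#'
#' Two distance engines are available: the all-pairs loop and a cell-list
#' spatial partition; they are exactly equivalent (same squared-distance
#' arithmetic) and the partition is the default.
#'
#' @param ensemble TrajectoryEnsemble (raw coordinates).
#' @param dna_mask SelectionMask of C1' atoms (default from topology).
#' @param ca_mask SelectionMask of CA atoms (default from topology).
#' @param cutoff contact cutoff in Angstrom (default 10).
#' @param window AnalysisWindow (default latter half).
#' @param engine "cells" or "all_pairs".
#' @return `ContactFrequencyMatrix`: numeric matrix nucleotides x residues in
#'   [0,1] with `chain:residue` dimnames; attributes cutoff, n_frames,
#'   row/column label data.frames.
#' @export
contact_frequency <- function(ensemble, dna_mask = NULL, ca_mask = NULL,
                              cutoff = 10, window = analysis_window(),
                              engine = c("cells", "all_pairs")) {
  engine <- match.arg(engine)
  if (cutoff <= 0) stop("cutoff must be positive")
  topo <- ensemble$topology
  if (is.null(dna_mask)) dna_mask <- make_selection(topo, label = "dna_c1p")
  if (is.null(ca_mask)) ca_mask <- make_selection(topo, label = "histone_ca")
  if (!length(dna_mask$indices) || !length(ca_mask$indices))
    stop("contact masks must be non-empty")
  widx <- resolve_window(ensemble, window)
  ni <- length(dna_mask$indices)
  nj <- length(ca_mask$indices)
  counts <- matrix(0L, ni, nj)
  total <- 0L
  for (k in seq_along(ensemble$trials)) {
    tr <- ensemble$trials[[k]]
    for (f in widx[[k]]) {
      P <- tr$coords[f, dna_mask$indices, , drop = FALSE]
      dim(P) <- c(ni, 3L)
      Q <- tr$coords[f, ca_mask$indices, , drop = FALSE]
      dim(Q) <- c(nj, 3L)
      hit <- if (engine == "cells") contact_hits_cells(P, Q, cutoff)
             else contact_hits_all_pairs(P, Q, cutoff)
      counts <- counts + hit
      total <- total + 1L
    }
  }
  freq <- counts / total
  rl <- label_df(topo, dna_mask$indices)
  cl <- label_df(topo, ca_mask$indices)
  dimnames(freq) <- list(paste0(rl$chain, ":", rl$residue_index),
                         paste0(cl$chain, ":", cl$residue_index))
  structure(freq, class = c("ContactFrequencyMatrix", "matrix"),
            cutoff = cutoff, n_frames = total,
            row_labels = rl, col_labels = cl)
}

label_df <- function(topology, idx) {
  data.frame(chain = topology$atoms$chain_id[idx],
             residue_index = topology$atoms$residue_index[idx],
             stringsAsFactors = FALSE)
}

# all-pairs engine: logical ni x nj, strict inequality at the cutoff
contact_hits_all_pairs <- function(P, Q, cutoff) {
  ni <- nrow(P); nj <- nrow(Q)
  hit <- matrix(FALSE, ni, nj)
  c2 <- cutoff^2
  for (i in seq_len(ni)) {
    d2 <- (Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2 + (Q[, 3] - P[i, 3])^2
    hit[i, ] <- d2 < c2
  }
  hit
}

# cell-list engine: bin Q into cubic cells of edge `cutoff`; only the 27
# neighbouring cells of a P point can contain contacts. Candidate pairs are
# gathered by vectorized integer cell keys and the squared distance of each
# candidate uses the same elementwise expression as the all-pairs loop, so
# the two engines return identical results.
contact_hits_cells <- function(P, Q, cutoff) {
  ni <- nrow(P); nj <- nrow(Q)
  hit <- matrix(FALSE, ni, nj)
  c2 <- cutoff^2
  qc <- floor(Q / cutoff)
  pc <- floor(P / cutoff)
  lo <- pmin(apply(qc, 2, min), apply(pc, 2, min)) - 1
  span <- pmax(apply(qc, 2, max), apply(pc, 2, max)) + 1 - lo + 1
  enc <- function(cells) {
    (cells[, 1] - lo[1]) +
      span[1] * ((cells[, 2] - lo[2]) + span[2] * (cells[, 3] - lo[3]))
  }
  qkey <- enc(qc)
  members <- split(seq_len(nj), qkey)
  ukey <- as.numeric(names(members))
  sizes <- lengths(members)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  doff <- offs[, 1] + span[1] * (offs[, 2] + span[2] * offs[, 3])
  # ni x 27 neighbour-cell keys, mapped to occupied cells in one match()
  nbr <- outer(enc(pc), doff, "+")
  cell_id <- match(as.vector(nbr), ukey)
  bead <- rep(seq_len(ni), times = 27)
  ok <- !is.na(cell_id)
  bead <- bead[ok]; cell_id <- cell_id[ok]
  if (length(bead)) {
    ps <- rep(bead, times = sizes[cell_id])
    qs <- unlist(members[cell_id], use.names = FALSE)
    d2 <- (Q[qs, 1] - P[ps, 1])^2 + (Q[qs, 2] - P[ps, 2])^2 +
          (Q[qs, 3] - P[ps, 3])^2
    sel <- d2 < c2
    hit[cbind(ps[sel], qs[sel])] <- TRUE
  }
  hit
}

#' Restrict a contact matrix to selected regions
#'
#' Rows (nucleotides) and columns (amino acids) are restricted by chain and
#' residue-range selections, e.g. the H2A C-terminal tail (residues 99-128).
#'
#' @param matrix ContactFrequencyMatrix.
#' @param rows,cols NULL (keep all) or data.frame(chain, from, to); multiple
#'   rows union.
#' @return Restricted ContactFrequencyMatrix.
#' @export
tail_contact_submatrix <- function(matrix, rows = NULL, cols = NULL) {
  rl <- attr(matrix, "row_labels")
  cl <- attr(matrix, "col_labels")
  ri <- restrict_labels(rl, rows)
  ci <- restrict_labels(cl, cols)
  if (!length(ri) || !length(ci))
    stop("empty restriction: no matching residues in the matrix")
  out <- matrix[ri, ci, drop = FALSE]
  structure(out, class = class(matrix),
            cutoff = attr(matrix, "cutoff"),
            n_frames = attr(matrix, "n_frames"),
            row_labels = rl[ri, , drop = FALSE],
            col_labels = cl[ci, , drop = FALSE])
}

restrict_labels <- function(lab, sel) {
  if (is.null(sel)) return(seq_len(nrow(lab)))
  keep <- rep(FALSE, nrow(lab))
  for (k in seq_len(nrow(sel))) {
    keep <- keep | (lab$chain == sel$chain[k] &
                    lab$residue_index >= sel$from[k] &
                    lab$residue_index <= sel$to[k])
  }
  which(keep)
}

#' Signed difference of two contact matrices over shared labels
#'
#' Elementwise `a - b` restricted to the row/column labels present in both
#' matrices (a variant lacking a dimer simply contributes no columns for the
#' deleted chains).
#'
#' @param a,b ContactFrequencyMatrix.
#' @return Matrix of differences in [-1, 1] with the shared labels.
#' @export
matrix_difference <- function(a, b) {
  shared_r <- intersect(rownames(a), rownames(b))
  shared_c <- intersect(colnames(a), colnames(b))
  if (!length(shared_r) || !length(shared_c))
    stop("contact matrices share no row/column labels")
  d <- a[shared_r, shared_c, drop = FALSE] - b[shared_r, shared_c, drop = FALSE]
  ra <- attr(a, "row_labels"); ca <- attr(a, "col_labels")
  structure(d, class = c("ContactFrequencyMatrix", "matrix"),
            cutoff = attr(a, "cutoff"), n_frames = NA_integer_,
            row_labels = ra[match(shared_r, rownames(a)), , drop = FALSE],
            col_labels = ca[match(shared_c, colnames(a)), , drop = FALSE])
}

#' Write a contact matrix in long TSV form
#'
#' Columns: nuc_chain, nuc_res, aa_chain, aa_res, frequency.
#' @param matrix ContactFrequencyMatrix.
#' @param path output path.
#' @export
write_contact_tsv <- function(matrix, path) {
  rl <- attr(matrix, "row_labels")
  cl <- attr(matrix, "col_labels")
  long <- data.frame(
    nuc_chain = rep(rl$chain, times = ncol(matrix)),
    nuc_res = rep(rl$residue_index, times = ncol(matrix)),
    aa_chain = rep(cl$chain, each = nrow(matrix)),
    aa_res = rep(cl$residue_index, each = nrow(matrix)),
    frequency = as.vector(matrix))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
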
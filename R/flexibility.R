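#' RMSD time series per trial and atom group
#'
#' For each trial and each group mask, computes
#' rmsd(t) = sqrt(mean over masked atoms of |x(t) - x(ref)|^2) on the
#' already-aligned coordinates; no per-group re-fitting is done, so the
#' series reflects deformation relative to the alignment convention used.
#' The reference is the first frame of each trial unless given.
#'
#' @param aligned AlignedEnsemble (convention "whole_complex" for per-histone
#'   panels; "histone_core_only" for DNA-deformation series).
#' @param groups named list of SelectionMask (default: one group per chain
#'   plus one pooled DNA group).
#' @param reference optional n x 3 reference coordinates.
#' @return data.frame (trial, time_ps, group, rmsd_A).
#' @export
rmsd_series <- function(aligned, groups = NULL, reference = NULL) {
  topo <- aligned$topology
  if (is.null(groups)) groups <- default_rmsd_groups(topo)
  if (!length(groups)) stop("no RMSD groups given")
  for (g in groups) if (!length(mask_indices(g, n_atoms(topo))))
    stop("empty mask in RMSD groups")
  out <- list()
  for (k in seq_along(aligned$trials)) {
    tr <- aligned$trials[[k]]
    ref <- if (is.null(reference)) frame_coords(tr, 1L) else reference
    for (gname in names(groups)) {
      idx <- mask_indices(groups[[gname]], n_atoms(topo))
      refg <- ref[idx, , drop = FALSE]
      nf <- n_frames(tr)
      vals <- numeric(nf)
      for (f in seq_len(nf)) {
        d <- tr$coords[f, idx, , drop = FALSE]
        dim(d) <- c(length(idx), 3L)
        vals[f] <- sqrt(mean(rowSums((d - refg)^2)))
      }
      out[[length(out) + 1L]] <- data.frame(
        trial = k, time_ps = tr$times, group = gname, rmsd_A = vals,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default RMSD groups: heavy non-tail atoms per histone chain + pooled DNA
#' @keywords internal
default_rmsd_groups <- function(topology,
                                region_table = default_region_table()) {
  atoms <- topology$atoms
  heavy <- !hydrogen_flag(atoms)
  groups <- list()
  base <- make_selection(topology, region_table, "align_all_no_tails")
  role <- unname(topology$chain_roles[atoms$chain_id])
  for (ch in histone_chains(topology)) {
    idx <- intersect(base$indices, which(atoms$chain_id == ch))
    if (length(idx)) groups[[paste0(topology$chain_roles[[ch]], "(", ch, ")")]] <-
      new_mask(idx, "custom")
  }
  dna_idx <- which(heavy & role %in% DNA_ROLES)
  if (length(dna_idx)) groups[["DNA"]] <- new_mask(dna_idx, "custom")
  groups
}

#' Per-nucleotide RMSF profile of DNA C1' atoms
#'
#' rmsf_i = sqrt(mean over pooled window frames of |x_i - <x_i>|^2), with the
#' mean structure <x_i> taken over the same pooled frames. With
#' `pool_trials = TRUE` (default) frames of all trials are pooled before the
#' mean; otherwise one profile per trial is returned, each about its own
#' trial mean.
#'
#' @param aligned AlignedEnsemble, histone-core-only convention (DNA is free
#'   to deform after the fit).
#' @param window AnalysisWindow (default latter half).
#' @param dna_mask SelectionMask of C1' atoms (default built from topology).
#' @param pool_trials pool frames of all trials before computing the mean.
#' @return data.frame (chain, residue_index, rmsf_A[, trial]).
#' @export
rmsf_profile <- function(aligned, window = analysis_window(),
                         dna_mask = NULL, pool_trials = TRUE) {
  topo <- aligned$topology
  if (is.null(dna_mask)) dna_mask <- make_selection(topo, label = "dna_c1p")
  idx <- dna_mask$indices
  if (!length(idx)) stop("empty C1' mask")
  widx <- resolve_window(aligned, window)
  lab <- data.frame(chain = topo$atoms$chain_id[idx],
                    residue_index = topo$atoms$residue_index[idx],
                    stringsAsFactors = FALSE)
  stack_trial <- function(k) {
    tr <- aligned$trials[[k]]
    w <- widx[[k]]
    x <- tr$coords[w, idx, , drop = FALSE]   # frames x beads x 3
    x
  }
  rmsf_of <- function(x) {
    mu <- apply(x, c(2, 3), mean)
    nf <- dim(x)[1]
    sq <- sweep(x, c(2, 3), mu)^2
    sqrt(apply(sq, 2, sum) / nf)
  }
  if (pool_trials) {
    xs <- lapply(seq_along(aligned$trials), stack_trial)
    x <- do.call(abind3, xs)
    cbind(lab, rmsf_A = rmsf_of(x))
  } else {
    out <- lapply(seq_along(aligned$trials), function(k) {
      cbind(lab, rmsf_A = rmsf_of(stack_trial(k)), trial = k)
    })
    do.call(rbind, out)
  }
}

# bind frames x beads x 3 arrays along dim 1
abind3 <- function(...) {
  xs <- list(...)
  nf <- vapply(xs, function(x) dim(x)[1], 1L)
  d <- dim(xs[[1]])
  out <- array(0, dim = c(sum(nf), d[2], d[3]))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}
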
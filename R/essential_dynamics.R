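#' Essential-dynamics PCA of DNA C1' coordinates
#'
#' Stacks the masked C1' coordinates of each window frame into a 3N vector
#' X(tau), pools frames across trials (the default; per-trial behind a flag),
#' and eigendecomposes the covariance of X. Eigenvector signs are fixed so
#' the largest-magnitude component of each mode is positive; within
#' numerically degenerate eigenvalues the ordering is by eigenvalue then by
#' first differing component, documented as arbitrary.
#'
#' @param aligned AlignedEnsemble (histone-core-only convention).
#' @param window AnalysisWindow for the covariance (default latter half).
#' @param dna_mask SelectionMask of the per-nucleotide atoms (default C1').
#' @param per_trial if TRUE, return a list of per-trial results.
#' @return `EssentialDynamics`: list(mean_structure N x 3, eigenvectors
#'   3N x 3N (columns), eigenvalues descending, N, labels).
#' @export
compute_modes <- function(aligned, window = analysis_window(),
                          dna_mask = NULL, per_trial = FALSE) {
  topo <- aligned$topology
  if (is.null(dna_mask)) dna_mask <- make_selection(topo, label = "dna_c1p")
  idx <- dna_mask$indices
  if (!length(idx)) stop("no atoms selected for PCA")
  widx <- resolve_window(aligned, window)
  if (per_trial) {
    res <- lapply(seq_along(aligned$trials), function(k)
      modes_from_matrix(stack_X(aligned, idx, widx, k), topo, idx))
    return(res)
  }
  X <- stack_X(aligned, idx, widx, seq_along(aligned$trials))
  modes_from_matrix(X, topo, idx)
}

# frames x 3N matrix, rows ordered (x1,y1,z1,x2,...) per frame
stack_X <- function(aligned, idx, widx, trials) {
  rows <- list()
  for (k in trials) {
    tr <- aligned$trials[[k]]
    w <- widx[[k]]
    x <- tr$coords[w, idx, , drop = FALSE]          # f x N x 3
    # aperm to f x 3 x N then flatten column-major: columns are x1,y1,z1,x2,...
    rows[[length(rows) + 1L]] <- matrix(aperm(x, c(1, 3, 2)), nrow = dim(x)[1])
  }
  do.call(rbind, rows)
}

modes_from_matrix <- function(X, topo, idx) {
  nf <- nrow(X)
  if (nf < 1L) stop("no frames in PCA window")
  if (3L * length(idx) > nf)
    warning("fewer pooled frames (", nf, ") than coordinates (",
            3L * length(idx), "); trailing modes are null")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nf
  e <- eigen(C, symmetric = TRUE)
  lam <- e$values
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(
    mean_structure = matrix(mu, ncol = 3, byrow = TRUE),
    eigenvectors = V,
    eigenvalues = lam,
    N = length(idx),
    atom_indices = idx,
    labels = data.frame(chain = topo$atoms$chain_id[idx],
                        residue_index = topo$atoms$residue_index[idx],
                        stringsAsFactors = FALSE),
    n_frames = nf), class = "EssentialDynamics")
}

#' @export
print.EssentialDynamics <- function(x, ...) {
  tot <- sum(pmax(x$eigenvalues, 0))
  cat("EssentialDynamics:", x$N, "beads,", x$n_frames, "pooled frames\n")
  top <- utils::head(x$eigenvalues, 3)
  cat("  leading eigenvalues (A^2):", paste(signif(top, 4), collapse = ", "),
      sprintf(" (%.1f%% of variance in mode 1)\n", 100 * top[1] / tot))
  invisible(x)
}

#' Project frames onto essential-dynamics modes
#'
#' S(tau, j) = (X(tau) - <X>) . v_j, evaluated for every frame of every
#' trial (including frames outside the covariance window, so full
#' trajectories can be drawn over a landscape).
#'
#' @param aligned AlignedEnsemble with the same mask/ordering used for
#'   [compute_modes()].
#' @param modes_result EssentialDynamics.
#' @param modes integer vector of mode indices (default 1:2).
#' @return data.frame (trial, frame, time_ps, then one `S<j>` column per mode,
#'   Angstrom).
#' @export
project_modes <- function(aligned, modes_result, modes = 1:2) {
  if (any(modes < 1L) || any(modes > ncol(modes_result$eigenvectors)))
    stop("mode index out of range")
  idx <- modes_result$atom_indices
  mu <- as.vector(t(modes_result$mean_structure))
  V <- modes_result$eigenvectors[, modes, drop = FALSE]
  out <- list()
  for (k in seq_along(aligned$trials)) {
    tr <- aligned$trials[[k]]
    x <- tr$coords[, idx, , drop = FALSE]
    m <- matrix(aperm(x, c(1, 3, 2)), nrow = dim(x)[1])
    S <- sweep(m, 2, mu) %*% V
    df <- data.frame(trial = k, frame = seq_len(nrow(S)), time_ps = tr$times)
    for (j in seq_along(modes)) df[[paste0("S", modes[j])]] <- S[, j]
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scott's rule bandwidth for a 2-D Gaussian KDE
#' @keywords internal
scott_bandwidth <- function(x) stats::sd(x) * length(x)^(-1 / 6)

#' Kernel-density landscape over the first two mode projections
#'
#' Gaussian-kernel density of the pooled (S1, S2) samples on a regular grid
#' covering the samples with at least a 3-bandwidth margin. The density is
#' reported as probability density (a -ln density surface is attached for
#' free-energy-style plots). Bandwidths follow Scott's rule by default.
#'
#' @param projections data.frame from [project_modes()] restricted to the
#'   analysis window (pass all frames to emulate full-trajectory overlays,
#'   but the landscape itself should use the window samples).
#' @param cols names of the two projection columns.
#' @param bandwidth NULL for Scott's rule, or numeric length-2 (kernel sd, A).
#' @param gridsize points per axis.
#' @return `FreeEnergyLandscape`: list(s1, s2, density, neg_log_density,
#'   bandwidth, samples).
#' @export
estimate_landscape <- function(projections, cols = c("S1", "S2"),
                               bandwidth = NULL, gridsize = 101) {
  s1 <- projections[[cols[1]]]
  s2 <- projections[[cols[2]]]
  if (length(s1) < 2L) stop("need at least 2 sample points")
  degenerate <- (max(s1) - min(s1) < 1e-12) && (max(s2) - min(s2) < 1e-12)
  if (degenerate) {
    warning("all projection samples identical; density is a delta-like peak")
    h <- c(1e-3, 1e-3)
  } else if (is.null(bandwidth)) {
    h <- c(scott_bandwidth(s1), scott_bandwidth(s2))
    h[h == 0] <- 1e-3
  } else h <- rep(bandwidth, length.out = 2)
  lims <- c(min(s1) - 3 * h[1], max(s1) + 3 * h[1],
            min(s2) - 3 * h[2], max(s2) + 3 * h[2])
  # MASS::kde2d's h argument is 4x the kernel standard deviation
  kd <- MASS::kde2d(s1, s2, h = 4 * h, n = gridsize, lims = lims)
  structure(list(s1 = kd$x, s2 = kd$y, density = kd$z,
                 neg_log_density = -log(pmax(kd$z, .Machine$double.xmin)),
                 bandwidth = h, bandwidth_rule = if (is.null(bandwidth))
                   "scott" else "fixed",
                 samples = cbind(s1, s2)),
            class = "FreeEnergyLandscape")
}

#' Evaluate the landscape's kernel density at arbitrary points
#'
#' Exact Gaussian-mixture evaluation over the stored samples (product
#' kernel, per-axis bandwidths as estimated).
#'
#' @param landscape FreeEnergyLandscape.
#' @param points matrix/data.frame with two columns (S1, S2).
#' @return Numeric density values.
#' @export
landscape_density_at <- function(landscape, points) {
  pts <- as.matrix(points)
  h <- landscape$bandwidth
  s <- landscape$samples
  vapply(seq_len(nrow(pts)), function(i) {
    mean(stats::dnorm(pts[i, 1], s[, 1], h[1]) *
         stats::dnorm(pts[i, 2], s[, 2], h[2]))
  }, numeric(1))
}

#' Highest-density-region membership of a point
#'
#' A point lies inside the `level` highest-density region when its density
#' exceeds the (1 - level) quantile of the density evaluated at the samples
#' themselves (the standard sample-based HDR approximation).
#'
#' @param landscape FreeEnergyLandscape.
#' @param point length-2 numeric.
#' @param level HDR probability mass (default 0.5).
#' @return logical.
#' @export
in_hdr <- function(landscape, point, level = 0.5) {
  dens_pt <- landscape_density_at(landscape, matrix(point, nrow = 1))
  dens_samples <- landscape_density_at(landscape, landscape$samples)
  thr <- stats::quantile(dens_samples, probs = 1 - level, names = FALSE)
  dens_pt >= thr
}

#' Per-nucleotide displacement arrows of a mode
#'
#' Reshapes eigenvector v_j to N x 3 displacement vectors, scaled for
#' visualization; per-bead norms are attached.
#'
#' @param modes_result EssentialDynamics.
#' @param mode mode index.
#' @param scale multiplicative factor.
#' @return data.frame (chain, residue_index, dx, dy, dz, norm).
#' @export
export_mode_arrows <- function(modes_result, mode = 1, scale = 1) {
  if (mode < 1L || mode > ncol(modes_result$eigenvectors))
    stop("mode index out of range")
  v <- matrix(modes_result$eigenvectors[, mode], ncol = 3, byrow = TRUE)
  v <- v * scale
  cbind(modes_result$labels,
        dx = v[, 1], dy = v[, 2], dz = v[, 3],
        norm = sqrt(rowSums(v^2)))
}
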
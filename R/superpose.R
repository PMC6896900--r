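#' Kabsch least-squares rigid-body superposition
#'
#' Finds the proper rotation R and translation t minimizing the RMSD between
#' `mobile` and `reference` over the masked atoms (orthogonal Procrustes with
#' det(R) = +1 enforced by sign-flipping the smallest singular vector).
#' Fitting is unweighted; atom correspondence is positional within the mask.
#'
#' @param mobile,reference n x 3 coordinate matrices in correspondence.
#' @param mask SelectionMask or integer atom indices; default all atoms.
#' @return `SuperpositionResult`: list(rotation 3x3, translation 3-vector,
#'   rmsd in Angstrom). Aligned mobile coordinates are
#'   `mobile %*% rotation + translation` (rows).
#' @export
kabsch_superpose <- function(mobile, reference, mask = NULL) {
  idx <- mask_indices(mask, nrow(mobile))
  if (nrow(mobile) != nrow(reference))
    stop("correspondence length mismatch between mobile and reference")
  A <- mobile[idx, , drop = FALSE]
  B <- reference[idx, , drop = FALSE]
  if (nrow(A) < 3L) stop("degenerate geometry: superposition needs >= 3 atoms")
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  if (collinear(A0) || collinear(B0))
    stop("degenerate geometry: masked atoms are collinear")
  H <- crossprod(A0, B0)            # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)         # applied as row-vector product x %*% R
  tvec <- as.vector(cb - ca %*% R)
  fitted <- sweep(A %*% R, 2, tvec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = tvec, rmsd = rmsd),
            class = "SuperpositionResult")
}

collinear <- function(X0, tol = 1e-8) {
  s <- svd(X0, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}

mask_indices <- function(mask, n) {
  if (is.null(mask)) return(seq_len(n))
  if (inherits(mask, "SelectionMask")) return(mask$indices)
  as.integer(mask)
}

#' Apply a superposition transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param fit SuperpositionResult.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2, fit$translation, "+")
}

#' Align every frame of an ensemble onto a reference
#'
#' Two conventions mirror the standard nucleosome-analysis setup:
#' * `"whole_complex"` (i): fit on all heavy atoms except histone tails;
#' * `"histone_core_only"` (ii): fit on histone-core heavy atoms only
#'   (DNA excluded), so DNA deformation survives the alignment.
#'
#' The fitted transform of each frame is applied to all atoms of the frame.
#'
#' @param ensemble TrajectoryEnsemble.
#' @param convention "whole_complex" or "histone_core_only", or a
#'   SelectionMask used directly as the fit mask.
#' @param reference n x 3 reference coordinates (default: first frame of each
#'   trial, the post-minimization structure).
#' @param region_table histone core/tail ranges for mask construction.
#' @return `AlignedEnsemble`: TrajectoryEnsemble plus per-frame transforms.
#' @export
align_ensemble <- function(ensemble, convention = c("whole_complex",
                                                    "histone_core_only"),
                           reference = NULL,
                           region_table = default_region_table()) {
  if (inherits(convention, "SelectionMask")) {
    fit_mask <- convention
    conv_label <- "custom"
  } else {
    conv_label <- match.arg(convention)
    lab <- if (conv_label == "whole_complex") "align_all_no_tails"
           else "align_histone_core_only"
    fit_mask <- make_selection(ensemble$topology, region_table, lab)
  }
  if (!length(fit_mask$indices))
    stop("alignment mask is empty for this topology")
  trials <- vector("list", length(ensemble$trials))
  transforms <- vector("list", length(ensemble$trials))
  for (k in seq_along(ensemble$trials)) {
    tr <- ensemble$trials[[k]]
    ref <- if (is.null(reference)) frame_coords(tr, 1L) else reference
    nf <- n_frames(tr)
    out <- tr$coords
    tf <- vector("list", nf)
    for (f in seq_len(nf)) {
      fr <- frame_coords(tr, f)
      fit <- tryCatch(kabsch_superpose(fr, ref, fit_mask),
                      error = function(e)
                        stop("alignment failed at trial ", k, " frame ", f,
                             ": ", conditionMessage(e)))
      out[f, , ] <- apply_transform(fr, fit)
      tf[[f]] <- fit
    }
    trials[[k]] <- list(times = tr$times, coords = out)
    transforms[[k]] <- tf
  }
  aligned <- trajectory_ensemble(ensemble$topology, trials,
                                 ensemble$sampling_interval)
  aligned$convention <- conv_label
  aligned$fit_mask <- fit_mask
  aligned$transforms <- transforms
  class(aligned) <- c("AlignedEnsemble", class(aligned))
  aligned
}

#' RMSD between two structures with separate fit and measure masks
#'
#' Superposes `coords_a` onto `coords_b` using `fit_mask`, then reports the
#' RMSD over `measure_mask` (default: the fit mask). Exposing both masks
#' lets all atom-subset interpretations of a published structure comparison
#' be tried.
#'
#' @param coords_a,coords_b n x 3 matrices in correspondence.
#' @param fit_mask,measure_mask SelectionMask or indices.
#' @return RMSD in Angstrom.
#' @export
structure_rmsd <- function(coords_a, coords_b, fit_mask = NULL,
                           measure_mask = NULL) {
  fit <- kabsch_superpose(coords_a, coords_b, fit_mask)
  midx <- mask_indices(if (is.null(measure_mask)) fit_mask else measure_mask,
                       nrow(coords_a))
  fitted <- apply_transform(coords_a, fit)
  sqrt(mean(rowSums((fitted[midx, , drop = FALSE] -
                     coords_b[midx, , drop = FALSE])^2)))
}
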
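# Kabsch superposition and rigid-body decomposition.

# Optimal proper rotation R and translation t minimizing ||(P R + t) - Q||^2
# over rows; reflections are excluded (det(R) = +1).
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(R = R, t = cq - as.numeric(cp %*% R))
}

apply_fit <- function(X, fit) sweep(X %*% fit$R, 2, fit$t, `+`)

check_fit_atoms <- function(xyz) {
  if (nrow(xyz) < 3)
    stop_allonet("fit selection needs at least 3 atoms", "allonet_numerical_error")
  if (sum(svd(sweep(xyz, 2, colMeans(xyz)))$d > 1e-8) < 2)
    stop_allonet("fit selection is collinear/degenerate", "allonet_numerical_error")
}

#' Least-squares superposition of an ensemble
#'
#' Each frame is rigid-body fitted (rotation + translation, proper rotations
#' only) onto the reference over the fit selection.  With
#' \code{reference = "mean"} a two-pass scheme is used: frames are first
#' fitted to the first frame, the mean structure is computed, and frames are
#' refitted to that mean.
#'
#' @param ensemble a `StructuralEnsemble`
#' @param fit_selection residue selection used for fitting (default: all)
#' @param atom_mode atoms used within the selection ("CA", "backbone",
#'   "heavy", "all")
#' @param reference a frame index, or "mean"
#' @return the superposed ensemble
#' @export
superpose_ensemble <- function(ensemble, fit_selection = NULL,
                               atom_mode = c("CA", "backbone", "heavy", "all"),
                               reference = "mean") {
  atom_mode <- match.arg(atom_mode)
  idx <- select_atoms(ensemble, fit_selection, atom_mode)
  if (length(idx) < 3) idx <- select_atoms(ensemble, fit_selection, "all")
  F <- n_frames(ensemble)
  get_sel <- function(co) co[idx, , drop = FALSE]

  fit_all_to <- function(xyz_mat, ref_sel) {
    out <- xyz_mat
    for (f in seq_len(F)) {
      co <- matrix(xyz_mat[f, ], ncol = 3, byrow = TRUE)
      fit <- kabsch(get_sel(co), ref_sel)
      out[f, ] <- flat_xyz(apply_fit(co, fit))
    }
    out
  }

  if (identical(reference, "mean")) {
    ref0 <- get_sel(frame_coords(ensemble, 1))
    check_fit_atoms(ref0)
    pass1 <- fit_all_to(ensemble$xyz, ref0)
    mean_co <- matrix(colMeans(pass1), ncol = 3, byrow = TRUE)
    xyz <- fit_all_to(ensemble$xyz, get_sel(mean_co))
  } else {
    ref <- get_sel(frame_coords(ensemble, as.integer(reference)))
    check_fit_atoms(ref)
    xyz <- fit_all_to(ensemble$xyz, ref)
  }
  new_ensemble(ensemble$atoms, xyz, labels = ensemble$labels)
}

#' RMSD between two coordinate sets (no fitting)
#' @param A,B n x 3 matrices
#' @export
coord_rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

#' Rigid-body decomposition of a moving subdomain
#'
#' Frames are superposed on \code{fit_selection}; for every frame the RMSD of
#' \code{probe_selection} to its reference pose is reported together with the
#' angle of the optimal proper rotation mapping the probe's reference pose
#' onto its frame pose (the subdomain's rigid-body rotation, in degrees).
#'
#' @param ensemble a `StructuralEnsemble`
#' @param fit_selection residues defining the fixed frame of reference
#' @param probe_selection residues of the moving subdomain
#' @param reference reference frame index (default 1)
#' @param atom_mode atom subset used ("CA" default)
#' @return data.frame with columns frame, rmsd (A), angle (degrees)
#' @export
rigid_body_decomposition <- function(ensemble, fit_selection, probe_selection,
                                     reference = 1L,
                                     atom_mode = c("CA", "backbone", "heavy", "all")) {
  atom_mode <- match.arg(atom_mode)
  fitted <- superpose_ensemble(ensemble, fit_selection, atom_mode, reference = reference)
  pidx <- select_atoms(fitted, probe_selection, atom_mode)
  if (length(pidx) < 3)
    stop_allonet("probe selection needs >= 3 atoms for a defined rotation",
                 "allonet_numerical_error")
  ref <- frame_coords(fitted, as.integer(reference))[pidx, , drop = FALSE]
  out <- data.frame(frame = seq_len(n_frames(fitted)), rmsd = NA_real_,
                    angle = NA_real_)
  for (f in seq_len(n_frames(fitted))) {
    cur <- frame_coords(fitted, f)[pidx, , drop = FALSE]
    out$rmsd[f] <- coord_rmsd(cur, ref)
    R <- kabsch(ref, cur)$R
    cosang <- (sum(diag(R)) - 1) / 2
    out$angle[f] <- acos(min(1, max(-1, cosang))) * 180 / pi
  }
  out
}
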
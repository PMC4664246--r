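# Solvent-accessible surface machinery shared by residue depth and SASA.

# Built-in van der Waals radii per element (Angstrom).
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
DEFAULT_VDW <- 1.70

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- DEFAULT_VDW
  unname(r)
}

# Deterministic Fibonacci lattice on the unit sphere; no RNG anywhere in the
# surface computation.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Exposed solvent-accessible surface points of a heavy-atom coordinate set.
# Returns the point cloud, the owning atom of each point, and each atom's
# exposed fraction.
sas_exposed_points <- function(xyz, radii, probe = 1.4, points_per_atom = 256L) {
  n <- nrow(xyz)
  unit <- fibonacci_sphere(points_per_atom)
  acc <- radii + probe
  pts <- vector("list", n)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(unit * acc[i], 2, xyz[i, ], `+`)
    others <- setdiff(seq_len(n), i)
    if (length(others)) {
      dc <- sqrt(rowSums(sweep(xyz[others, , drop = FALSE], 2, xyz[i, ])^2))
      near <- others[dc < acc[i] + acc[others]]
      exposed <- rep(TRUE, nrow(p))
      for (j in near) {
        d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
        exposed <- exposed & d2 >= acc[j]^2
        if (!any(exposed)) break
      }
    } else exposed <- rep(TRUE, nrow(p))
    frac[i] <- mean(exposed)
    pts[[i]] <- p[exposed, , drop = FALSE]
  }
  cloud <- do.call(rbind, pts)
  owner <- rep(seq_len(n), vapply(pts, nrow, integer(1)))
  list(points = cloud, owner = owner, fraction = frac, accessible_radius = acc)
}

#' Exposed solvent-accessible surface points of a structure
#'
#' Sphere-sampled points on each heavy atom's solvent-accessible sphere
#' (radius vdW + probe), retained iff they fall outside every other atom's
#' accessible sphere.  Sampling uses a deterministic Fibonacci lattice.
#'
#' @param structure a `Structure` (heavy atoms are used)
#' @param probe probe radius (Angstrom, default 1.4)
#' @param points_per_atom sampling density
#' @return list: `points` (m x 3), `owner` (atom index within the heavy-atom
#'   subset), `fraction` (per-atom exposed fraction), `atom_idx`
#' @export
surface_points <- function(structure, probe = 1.4, points_per_atom = 256L) {
  heavy <- which(structure$atoms$is_heavy)
  if (!length(heavy)) stop_allonet("no heavy atoms", "allonet_validation_error")
  xyz <- structure$xyz[heavy, , drop = FALSE]
  radii <- vdw_radius(structure$atoms$element[heavy])
  out <- sas_exposed_points(xyz, radii, probe, points_per_atom)
  out$atom_idx <- heavy
  out
}

#' Shrake-Rupley style solvent-accessible surface area
#'
#' Per-atom SASA = exposed fraction x 4 pi (r + probe)^2, deterministic
#' sphere sampling on heavy atoms; hydrogens are ignored.
#'
#' @inheritParams surface_points
#' @return list: `atom_sasa` (per heavy atom, A^2), `total`, `residue` (per
#'   residue data.frame)
#' @export
shrake_sasa <- function(structure, probe = 1.4, points_per_atom = 256L) {
  sp <- surface_points(structure, probe, points_per_atom)
  sasa <- sp$fraction * 4 * pi * sp$accessible_radius^2
  res <- structure$atoms$res_index[sp$atom_idx]
  res_sasa <- tapply(sasa, res, sum)
  rt <- residue_table(structure)
  val <- rep(0, nrow(rt))
  val[as.integer(names(res_sasa))] <- as.numeric(res_sasa)
  list(atom_sasa = sasa, total = sum(sasa),
       residue = profile_frame(structure, val, "sasa"))
}

# Depth of each heavy atom: distance from the atom centre to the nearest
# exposed surface point, minus the atom's own accessible radius, floored at
# zero -- surface atoms score ~0, buried atoms the extra distance their
# accessible sphere sits below the surface.
atom_depths <- function(xyz, radii, probe, points_per_atom) {
  sp <- sas_exposed_points(xyz, radii, probe, points_per_atom)
  if (!nrow(sp$points))
    stop_allonet("no exposed surface points found", "allonet_internal_error")
  n <- nrow(xyz)
  depth <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (sp$points[, 1] - xyz[i, 1])^2 + (sp$points[, 2] - xyz[i, 2])^2 +
      (sp$points[, 3] - xyz[i, 3])^2
    depth[i] <- max(0, sqrt(min(d2)) - sp$accessible_radius[i])
  }
  depth
}

#' Ensemble-averaged residue depth profile
#'
#' Atom depth = distance to the nearest exposed solvent-accessible surface
#' point of the same snapshot (less the atom's own accessible radius,
#' floored at 0); residue depth = mean over its heavy atoms; the profile
#' averages over snapshots.
#'
#' @param ensemble a `StructuralEnsemble` or `Structure`
#' @param probe probe radius (Angstrom)
#' @param points_per_atom surface sampling density
#' @return per-residue profile data.frame (value column `depth`, A)
#' @export
residue_depth_profile <- function(ensemble, probe = 1.4, points_per_atom = 256L) {
  ensemble <- as_ensemble(ensemble)
  heavy <- which(ensemble$atoms$is_heavy)
  radii <- vdw_radius(ensemble$atoms$element[heavy])
  res <- ensemble$atoms$res_index[heavy]
  acc <- matrix(0, length(heavy), n_frames(ensemble))
  for (f in seq_len(n_frames(ensemble))) {
    xyz <- frame_coords(ensemble, f)[heavy, , drop = FALSE]
    acc[, f] <- atom_depths(xyz, radii, probe, points_per_atom)
  }
  atom_mean <- rowMeans(acc)
  res_depth <- tapply(atom_mean, res, mean)
  val <- rep(NA_real_, n_residues(ensemble))
  val[as.integer(names(res_depth))] <- as.numeric(res_depth)
  profile_frame(ensemble, val, "depth")
}

#' Differential residue depth between two states
#'
#' \eqn{\Delta RD_i = RD_A(i) - RD_B(i)}; positive values mark residues more
#' buried (more protected) in state A.
#'
#' @param profile_a,profile_b depth profiles over the same residue universe
#' @return per-residue profile data.frame (value column `delta_depth`)
#' @export
differential_depth <- function(profile_a, profile_b) {
  key <- function(p) paste(p$chain, p$resno, p$insert, sep = ":")
  if (!identical(key(profile_a), key(profile_b)))
    stop_allonet("profiles cover different residue universes",
                 "allonet_consistency_error")
  out <- profile_a[, c("chain", "resno", "insert", "resid")]
  out$delta_depth <- profile_a[[ncol(profile_a)]] - profile_b[[ncol(profile_b)]]
  out
}

#' Sign agreement between differential depth and HDX protection
#'
#' Residues with \eqn{\Delta RD > 0} are predicted protected-in-A, with
#' \eqn{\Delta RD < 0} protected-in-B.  The HDX class is protected-in-A for
#' peak ratio > \code{protected_hi} (default 1.1), protected-in-B for ratio
#' < \code{protected_lo} (default 1.0); ratios in between are indeterminate
#' and excluded from the denominator.
#'
#' @param delta a differential depth profile (from [differential_depth()])
#' @param hdx data.frame with columns `resno` (optionally `chain`) and
#'   `ratio`, or a named numeric vector keyed by residue number
#' @param protected_hi,protected_lo HDX thresholds
#' @return list: `agreement` fraction, `n_compared`, `table` (contingency
#'   counts), `detail` per-residue data.frame
#' @export
hdx_sign_agreement <- function(delta, hdx, protected_hi = 1.1, protected_lo = 1.0) {
  if (is.numeric(hdx) && !is.null(names(hdx)))
    hdx <- data.frame(resno = as.integer(names(hdx)), ratio = as.numeric(hdx))
  if (any(hdx$ratio <= 0))
    stop_allonet("HDX peak ratios must be positive", "allonet_validation_error")
  idx <- match(hdx$resno, delta$resno)
  ok <- !is.na(idx)
  if (!any(ok))
    stop_allonet("no overlap between the depth profile and the HDX table",
                 "allonet_validation_error")
  hdx <- hdx[ok, , drop = FALSE]; idx <- idx[ok]
  drd <- delta$delta_depth[idx]
  pred <- ifelse(drd > 0, "A", ifelse(drd < 0, "B", NA))
  obs <- ifelse(hdx$ratio > protected_hi, "A",
                ifelse(hdx$ratio < protected_lo, "B", NA))
  use <- !is.na(pred) & !is.na(obs)
  detail <- data.frame(resno = hdx$resno, delta_depth = drd, ratio = hdx$ratio,
                       predicted = pred, observed = obs, compared = use)
  tab <- table(predicted = factor(pred[use], c("A", "B")),
               observed = factor(obs[use], c("A", "B")))
  list(agreement = if (any(use)) mean(pred[use] == obs[use]) else NA_real_,
       n_compared = sum(use), n_excluded = sum(!use), table = tab,
       detail = detail)
}
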
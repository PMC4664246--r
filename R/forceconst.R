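#' Mean-distance series of a residue or atom
#'
#' For every frame, the mean distance from the target to all atoms/residues
#' outside its own residue.  In residue (C-alpha) mode the sequence
#' neighbours i-1 and i+1 are also excluded, because those distances are
#' nearly constant and carry no fluctuation signal.
#'
#' @param ensemble a `StructuralEnsemble` (>= 2 frames for downstream use)
#' @param target residue key/index (residue mode) or atom index (atom mode)
#' @param unit "residue" (C-alpha positions) or "atom"
#' @return numeric per-frame series (Angstrom)
#' @export
mean_distance_series <- function(ensemble, target, unit = c("residue", "atom")) {
  unit <- match.arg(unit)
  atoms <- ensemble$atoms
  if (unit == "residue") {
    ridx <- resolve_residues(ensemble, target)
    if (length(ridx) != 1) stop_allonet("one target residue expected", "allonet_parameter_error")
    ca <- select_atoms(ensemble, NULL, "CA")
    if (length(ca) < 4)
      stop_allonet("too few residues for CA-mode mean distances",
                   "allonet_insufficient_data")
    res_of <- atoms$res_index[ca]
    self <- which(res_of == ridx)
    if (!length(self)) stop_allonet("target residue has no CA atom", "allonet_parameter_error")
    chain_t <- atoms$chain[ca][self[1]]
    neigh <- which(abs(res_of - ridx) == 1 & atoms$chain[ca] == chain_t)
    partners <- ca[-c(self, neigh)]
    if (length(partners) < 1)
      stop_allonet("no distance partners left", "allonet_insufficient_data")
    t_atom <- ca[self[1]]
  } else {
    t_atom <- as.integer(target)
    partners <- which(atoms$is_heavy & atoms$res_index != atoms$res_index[t_atom])
    # CA-CA distances to sequence neighbours are nearly constant and are
    # excluded from the calculation in every mode
    if (atoms$elety[t_atom] == "CA") {
      tr <- atoms$res_index[t_atom]; tc <- atoms$chain[t_atom]
      partners <- partners[!(atoms$elety[partners] == "CA" &
                               atoms$chain[partners] == tc &
                               abs(atoms$res_index[partners] - tr) == 1)]
    }
    if (!length(partners))
      stop_allonet("no distance partners left", "allonet_insufficient_data")
  }
  F <- n_frames(ensemble)
  out <- numeric(F)
  tc <- cbind(3 * (t_atom - 1) + 1, 3 * (t_atom - 1) + 2, 3 * t_atom)
  pc <- cbind(3 * (partners - 1) + 1, 3 * (partners - 1) + 2, 3 * partners)
  for (f in seq_len(F)) {
    tp <- ensemble$xyz[f, tc]
    pp <- matrix(ensemble$xyz[f, t(pc)], ncol = 3, byrow = TRUE)
    out[f] <- mean(sqrt((pp[, 1] - tp[1])^2 + (pp[, 2] - tp[2])^2 + (pp[, 3] - tp[3])^2))
  }
  out
}

#' Residue force-constant (rigidity) profile
#'
#' Converts fluctuations of mean distances into per-residue force constants
#' \eqn{k_i = 3 k_B T / \langle (d_i - \langle d_i \rangle)^2 \rangle}.  In
#' all-atom mode each heavy atom gets its own mean-distance series (to all
#' heavy atoms of other residues) and the residue averages its atoms' force
#' constants; CA mode uses the C-alpha series with sequence neighbours
#' excluded.  Variance is the population variance over frames.
#'
#' Zero-variance units are capped at \code{cap} rather than infinity so peak
#' detection downstream stays finite.
#'
#' @param ensemble a `StructuralEnsemble` with >= 2 frames
#' @param mode "all-atom" (default) or "CA"
#' @param temperature Kelvin
#' @param cap force-constant cap for zero-variance units
#' @return per-residue profile data.frame (value column `k`,
#'   kcal mol^-1 A^-2) with attributes `temperature` and `kBT`
#' @export
force_constant_profile <- function(ensemble, mode = c("all-atom", "CA"),
                                   temperature = 300, cap = 1e6) {
  mode <- match.arg(mode)
  if (n_frames(ensemble) < 2)
    stop_allonet("need >= 2 frames", "allonet_insufficient_data")
  kBT <- .kB * temperature
  atoms <- ensemble$atoms
  nres <- n_residues(ensemble)
  F <- n_frames(ensemble)

  if (mode == "CA") {
    v <- vapply(seq_len(nres), function(r) {
      d <- mean_distance_series(ensemble, r, "residue")
      mean((d - mean(d))^2)
    }, numeric(1))
    if (any(v <= 0)) warning("zero-variance distance series: force constant capped")
    val <- ifelse(v > 0, pmin(cap, 3 * kBT / v), cap)
  } else {
    heavy <- which(atoms$is_heavy)
    # per-frame heavy-atom distance matrix; series of mean distances to
    # atoms of other residues, one series per heavy atom
    nh <- length(heavy)
    res_h <- atoms$res_index[heavy]
    same <- outer(res_h, res_h, `==`)
    # sequence-neighbour CA-CA exclusion (see mean_distance_series)
    is_ca <- atoms$elety[heavy] == "CA"
    ch <- atoms$chain[heavy]
    nbr_ca <- outer(is_ca, is_ca, `&`) & outer(ch, ch, `==`) &
      abs(outer(res_h, res_h, `-`)) == 1
    same <- same | nbr_ca
    series <- matrix(0, nh, F)
    for (f in seq_len(F)) {
      co <- frame_coords(ensemble, f)[heavy, , drop = FALSE]
      D <- as.matrix(stats::dist(co))
      D[same] <- NA
      series[, f] <- rowMeans(D, na.rm = TRUE)
    }
    v <- rowMeans((series - rowMeans(series))^2)
    k_atom <- ifelse(v > 0, pmin(cap, 3 * kBT / v), cap)
    if (any(v <= 0)) warning("zero-variance distance series: force constant capped")
    val <- as.numeric(tapply(k_atom, res_h, mean))
  }
  out <- profile_frame(ensemble, val, "k")
  attr(out, "temperature") <- temperature
  attr(out, "kBT") <- kBT
  attr(out, "mode") <- mode
  out
}

#' Detect peaks in a per-residue profile
#'
#' Local maxima strictly greater than every other value within a
#' \code{window}-residue flank on both sides, and at least
#' \code{min_prominence} times the profile maximum.
#'
#' @param profile per-residue profile data.frame (last column is the value)
#'   or a bare numeric vector
#' @param window flank half-width in residues
#' @param min_prominence height threshold as a fraction of the profile max
#' @return data.frame of peaks (position, value) of class `peak_set`
#' @export
detect_profile_peaks <- function(profile, window = 3L, min_prominence = 0.5) {
  v <- if (is.data.frame(profile)) profile[[ncol(profile)]] else as.numeric(profile)
  n <- length(v)
  if (n < window) stop_allonet("profile shorter than window", "allonet_parameter_error")
  thr <- min_prominence * max(v, na.rm = TRUE)
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next   # boundary maxima are not peaks
    if (is.na(v[i]) || v[i] < thr) next
    fl <- v[max(1, i - window):min(n, i + window)]
    fl <- fl[-(i - max(1, i - window) + 1)]
    if (all(v[i] > fl, na.rm = TRUE)) is_peak[i] <- TRUE
  }
  idx <- which(is_peak)
  out <- if (is.data.frame(profile)) {
    cbind(profile[idx, , drop = FALSE], position = idx)
  } else data.frame(position = idx, value = v[idx])
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "min_prominence") <- min_prominence
  class(out) <- c("peak_set", "data.frame")
  out
}
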
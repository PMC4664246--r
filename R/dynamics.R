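#' Per-residue B-factor profile of a superposed ensemble
#'
#' \eqn{B_i = (8\pi^2/3) \langle |\Delta r_i|^2 \rangle} where
#' \eqn{\Delta r_i} is the deviation of atom i from its ensemble-mean
#' position; the residue value averages its selected atoms.
#'
#' @param ensemble superposed `StructuralEnsemble`
#' @param atom_mode "CA" or "heavy"
#' @return per-residue profile data.frame (value column `bfactor`, A^2)
#' @export
bfactor_profile <- function(ensemble, atom_mode = c("CA", "heavy")) {
  atom_mode <- match.arg(atom_mode)
  if (n_frames(ensemble) < 2)
    warning("single-frame ensemble: B-factors are all zero")
  idx <- select_atoms(ensemble, NULL, atom_mode)
  X <- ensemble$xyz
  Xc <- sweep(X, 2, colMeans(X))
  msf_coord <- colMeans(Xc^2)                       # per-coordinate variance
  msf_atom <- msf_coord[seq(1, ncol(X), 3)] + msf_coord[seq(2, ncol(X), 3)] +
    msf_coord[seq(3, ncol(X), 3)]                   # <|dr|^2> per atom
  b_atom <- (8 * pi^2 / 3) * msf_atom
  res <- ensemble$atoms$res_index[idx]
  b_res <- tapply(b_atom[idx], res, mean)
  val <- rep(NA_real_, n_residues(ensemble))
  val[as.integer(names(b_res))] <- as.numeric(b_res)
  profile_frame(ensemble, val, "bfactor")
}

#' Residue cross-correlation (DCCM) of a superposed ensemble
#'
#' \eqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#' \sqrt{\langle|\Delta r_i|^2\rangle \langle|\Delta r_j|^2\rangle}}
#' computed on C-alpha atoms (or each residue's single atom for toy traces).
#' Zero-variance residues get \eqn{C_{ij} = 0} off-diagonal with a warning.
#'
#' @param ensemble superposed ensemble with >= 2 frames
#' @param atom_mode "CA" (residues without a CA are represented by their
#'   first heavy atom)
#' @return a `CrossCorrelationMatrix` with residue-key dimnames
#' @export
cross_correlation <- function(ensemble, atom_mode = "CA") {
  if (n_frames(ensemble) < 2)
    stop_allonet("need >= 2 frames", "allonet_insufficient_data")
  atoms <- ensemble$atoms
  idx <- vapply(split(seq_len(nrow(atoms)), atoms$res_index), function(ii) {
    ca <- ii[atoms$elety[ii] == "CA"]
    if (length(ca)) ca[1] else ii[atoms$is_heavy[ii]][1]
  }, integer(1))
  idx <- idx[order(as.integer(names(idx)))]
  n <- length(idx)
  cols <- as.numeric(t(cbind(3 * (idx - 1) + 1, 3 * (idx - 1) + 2, 3 * idx)))
  X <- ensemble$xyz[, cols, drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / nrow(Xc)
  i1 <- seq(1, 3 * n, 3)
  tr <- S[i1, i1] + S[i1 + 1, i1 + 1] + S[i1 + 2, i1 + 2]
  v <- diag(tr)
  bad <- v <= 0
  if (any(bad)) {
    warning(sprintf("%d zero-variance residue(s): correlations set to 0", sum(bad)))
    v[bad] <- 1
  }
  C <- tr / sqrt(outer(v, v))
  if (any(bad)) { C[bad, ] <- 0; C[, bad] <- 0 }
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  keys <- atoms$residue_key[idx]
  dimnames(C) <- list(keys, keys)
  class(C) <- c("CrossCorrelationMatrix", class(C))
  C
}

#' Principal component analysis of a superposed ensemble
#'
#' Eigendecomposition of the 3n x 3n coordinate covariance (sample
#' covariance, denominator F - 1).  The largest-variance components are the
#' lowest-frequency modes.
#'
#' @param ensemble superposed ensemble with >= 2 frames
#' @param atom_set "CA" or "backbone"
#' @return object of class `pca_result`: eigenvalues (A^2, descending),
#'   orthonormal mode vectors (columns), mean coordinates, variance
#'   fractions, the atom indices used
#' @export
pca_modes <- function(ensemble, atom_set = c("CA", "backbone")) {
  atom_set <- match.arg(atom_set)
  if (n_frames(ensemble) < 2)
    stop_allonet("need >= 2 frames for PCA", "allonet_insufficient_data")
  idx <- select_atoms(ensemble, NULL, atom_set)
  if (!length(idx)) idx <- select_atoms(ensemble, NULL, "all")
  cols <- as.numeric(t(cbind(3 * (idx - 1) + 1, 3 * (idx - 1) + 2, 3 * idx)))
  X <- ensemble$xyz[, cols, drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  structure(list(values = vals, vectors = e$vectors, mean = mu,
                 var_frac = vals / sum(vals), atom_idx = idx,
                 atoms = ensemble$atoms[idx, , drop = FALSE],
                 trace = sum(diag(S))),
            class = "pca_result")
}

#' Low-frequency mode mobility profile
#'
#' Per-residue displacement amplitude
#' \eqn{\sqrt{\sum_m \lambda_m |v_{m,i}|^2}} over the top \code{n_modes}
#' largest-variance (lowest-frequency) principal components, averaged over
#' each residue's atoms.
#'
#' @param pca a `pca_result`
#' @param n_modes number of modes (default 3)
#' @return per-residue profile data.frame (value column `mobility`, A)
#' @export
mode_mobility_profile <- function(pca, n_modes = 3L) {
  m <- min(n_modes, length(pca$values))
  if (n_modes > length(pca$values))
    stop_allonet("n_modes exceeds available modes", "allonet_parameter_error")
  V <- pca$vectors[, seq_len(m), drop = FALSE]
  lam <- pca$values[seq_len(m)]
  n <- nrow(V) / 3
  amp2 <- matrix(0, n, 1)
  i1 <- seq(1, 3 * n, 3)
  contrib <- V^2 %*% matrix(lam)     # per coordinate
  amp_atom2 <- contrib[i1] + contrib[i1 + 1] + contrib[i1 + 2]
  res <- pca$atoms$res_index
  amp_res <- tapply(amp_atom2, res, mean)
  rt <- pca$atoms[!duplicated(pca$atoms$res_index),
                  c("chain", "resno", "insert", "resid")]
  rownames(rt) <- NULL
  rt$mobility <- sqrt(as.numeric(amp_res[as.character(sort(unique(res)))]))
  rt
}

#' Density of states over (energy, rigid-body RMSD)
#'
#' 2-D histogram of a per-frame scalar (e.g. an energy) against a per-frame
#' rigid-body RMSD, with peak detection (8-neighbour local maxima above a
#' fraction of the global maximum) and basin populations by nearest-peak
#' assignment of occupied bins.
#'
#' @param energy_series,rmsd_series equal-length per-frame numerics
#' @param bins number of bins per axis (default 50)
#' @param peak_frac detection threshold as a fraction of the maximum count
#' @return object of class `density_of_states`: counts matrix, bin edges,
#'   peaks data.frame (bin centers, height, population fraction)
#' @export
density_of_states <- function(energy_series, rmsd_series, bins = 50L,
                              peak_frac = 0.1) {
  if (length(energy_series) != length(rmsd_series))
    stop_allonet("series lengths differ", "allonet_consistency_error")
  n <- length(energy_series)
  brk <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1] - 1e-9 * max(1, abs(r[1])), r[2] + 1e-9 * max(1, abs(r[2])),
        length.out = bins + 1L)
  }
  ex <- brk(energy_series); rx <- brk(rmsd_series)
  ie <- findInterval(energy_series, ex, rightmost.closed = TRUE)
  ir <- findInterval(rmsd_series, rx, rightmost.closed = TRUE)
  counts <- matrix(0L, bins, bins)
  for (k in seq_len(n)) counts[ie[k], ir[k]] <- counts[ie[k], ir[k]] + 1L
  # smooth with a 3x3 box before peak picking: raw bin counts are Poisson
  # noisy and would fragment one basin into many spurious local maxima
  sm <- matrix(0, bins, bins)
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    sm[i, j] <- mean(counts[max(1, i - 1):min(bins, i + 1),
                            max(1, j - 1):min(bins, j + 1)])
  }
  mx <- max(sm)
  pk <- matrix(FALSE, bins, bins)
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    if (sm[i, j] < peak_frac * mx || sm[i, j] == 0) next
    nb <- sm[max(1, i - 1):min(bins, i + 1), max(1, j - 1):min(bins, j + 1)]
    if (sm[i, j] == max(nb)) pk[i, j] <- TRUE
  }
  # greedy minimum-separation merge, highest peak first
  pidx <- which(pk, arr.ind = TRUE)
  if (nrow(pidx) > 1) {
    ord <- order(-sm[pidx], -counts[pidx])
    pidx <- pidx[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(pidx))
    for (b in 2:nrow(pidx)) for (a in seq_len(b - 1)) {
      if (keep[a] && keep[b] &&
          max(abs(pidx[a, ] - pidx[b, ])) <= 3) keep[b] <- FALSE
    }
    pidx <- pidx[keep, , drop = FALSE]
  }
  mid <- function(edges) (edges[-1] + edges[-length(edges)]) / 2
  emid <- mid(ex); rmid <- mid(rx)
  # basin population: occupied bins assigned to the nearest peak in
  # (standardized) bin-index space
  pop <- rep(0, nrow(pidx))
  occ <- which(counts > 0, arr.ind = TRUE)
  if (nrow(pidx)) {
    for (k in seq_len(nrow(occ))) {
      d2 <- (pidx[, 1] - occ[k, 1])^2 + (pidx[, 2] - occ[k, 2])^2
      w <- which.min(d2)
      pop[w] <- pop[w] + counts[occ[k, 1], occ[k, 2]]
    }
    pop <- pop / n
  }
  peaks <- data.frame(energy = emid[pidx[, 1]], rmsd = rmid[pidx[, 2]],
                      height = counts[pidx], fraction = pop)
  peaks <- peaks[order(-peaks$fraction), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(counts = counts, energy_edges = ex, rmsd_edges = rx,
                 peaks = peaks, n_frames = n),
            class = "density_of_states")
}
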
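#' Anisotropic network model with analytic covariance
#'
#' Builds the ANM Hessian on C-alpha nodes (harmonic springs of force
#' constant \code{gamma} between nodes within \code{cutoff}), removes the six
#' rigid-body modes by a relative eigenvalue threshold, and returns the
#' analytic fluctuation covariance \eqn{k_B T H^+} (3N x 3N, A^2).  This is
#' the ground-truth model behind the synthetic Gaussian ensembles used to
#' validate every estimator in the package.
#'
#' @param structure a `Structure`; its C-alpha atoms become the nodes (all
#'   atoms are used when no CA atoms are present)
#' @param cutoff spring cutoff in Angstrom
#' @param gamma spring force constant, kcal mol^-1 A^-2
#' @param temperature Kelvin
#' @param mode_tol relative eigenvalue threshold below which modes are
#'   treated as rigid-body modes and discarded
#' @return object of class `anm_model` with elements `atoms`, `mean_xyz`,
#'   `hessian`, `covariance`, `eigen`, `kBT`
#' @export
anm_covariance <- function(structure, cutoff = 13, gamma = 1, temperature = 300,
                           mode_tol = 1e-8) {
  ca <- which(structure$atoms$elety == "CA")
  nodes <- if (length(ca) >= 3) subset_atoms(structure, ca) else structure
  x <- nodes$xyz
  n <- nrow(x)
  if (n < 3) stop_allonet("need at least 3 nodes", "allonet_model_error")
  cen <- sweep(x, 2, colMeans(x))
  if (sum(svd(cen)$d > 1e-8) < 2)
    stop_allonet("nodes are collinear: ANM is degenerate", "allonet_model_error")

  d <- as.matrix(stats::dist(x))
  contact <- d <= cutoff & upper.tri(d)
  # connectivity check on the contact graph
  g <- igraph::graph_from_adjacency_matrix(d <= cutoff, mode = "undirected", diag = FALSE)
  if (igraph::components(g)$no > 1L)
    stop_allonet("contact graph disconnected at this cutoff", "allonet_model_error")

  H <- matrix(0, 3 * n, 3 * n)
  for (p in which(contact)) {
    i <- (p - 1) %% n + 1; j <- (p - 1) %/% n + 1
    dv <- x[i, ] - x[j, ]
    blk <- -gamma * tcrossprod(dv) / sum(dv^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk; H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  e <- eigen(H, symmetric = TRUE)
  keep <- e$values > mode_tol * max(e$values)
  kBT <- .kB * temperature
  V <- e$vectors[, keep, drop = FALSE]
  covariance <- kBT * V %*% (t(V) / e$values[keep])
  structure(list(atoms = nodes$atoms, mean_xyz = nodes$xyz, hessian = H,
                 covariance = covariance,
                 eigen = list(values = e$values, n_kept = sum(keep)),
                 cutoff = cutoff, gamma = gamma, temperature = temperature,
                 kBT = kBT),
            class = "anm_model")
}

#' Sample a Gaussian ensemble from an ANM model
#'
#' Frames are the model's mean coordinates plus correlated Gaussian deviates
#' with exactly the model covariance; reproducible for a fixed seed.
#'
#' @param model an `anm_model`
#' @param n_frames number of frames (>= 1)
#' @param seed RNG seed
#' @return a [new_ensemble()] over the model's node atoms
#' @export
sample_gaussian_ensemble <- function(model, n_frames, seed = 1L) {
  if (n_frames < 1) stop_allonet("n_frames must be >= 1", "allonet_parameter_error")
  ev <- eigen(model$covariance, symmetric = TRUE)
  keep <- ev$values > 1e-12 * max(ev$values)
  L <- ev$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev$values[keep]), sum(keep))
  mu <- flat_xyz(model$mean_xyz)
  with_op_seed(seed, "sample_gaussian_ensemble", {
    Z <- matrix(stats::rnorm(n_frames * ncol(L)), n_frames)
    xyz <- sweep(Z %*% t(L), 2, mu, `+`)
    new_ensemble(model$atoms, xyz)
  })
}

#' Analytic cross-correlation matrix of an ANM model
#'
#' \eqn{C_{ij} = tr(\Sigma_{ij}) / \sqrt{tr(\Sigma_{ii}) tr(\Sigma_{jj})}}
#' from the 3x3 blocks of the model covariance; the closed-form oracle for
#' the ensemble estimator in [cross_correlation()].
#'
#' @param model an `anm_model`
#' @return a `CrossCorrelationMatrix` (symmetric, unit diagonal)
#' @export
analytic_cross_correlation <- function(model) {
  S <- model$covariance
  n <- nrow(S) / 3
  tr <- S[seq(1, 3 * n, 3), seq(1, 3 * n, 3)] +
        S[seq(2, 3 * n, 3), seq(2, 3 * n, 3)] +
        S[seq(3, 3 * n, 3), seq(3, 3 * n, 3)]
  v <- diag(tr)
  if (any(v <= 0))
    stop_allonet("zero-variance node: correlation undefined", "allonet_model_error")
  C <- tr / sqrt(outer(v, v))
  keys <- model$atoms$residue_key[!duplicated(model$atoms$res_index)]
  dimnames(C) <- list(keys, keys)
  class(C) <- c("CrossCorrelationMatrix", class(C))
  C
}
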
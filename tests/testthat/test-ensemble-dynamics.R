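# Superposition, B-factors, cross-correlation, PCA, mobility, rigid-body
# decomposition, and density-of-states population analysis.

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rot_axis <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2)); th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

test_that("superposition exactly recovers a rotated+translated copy", {
  toy <- build_toy_protein(8, "helix", 2, seed = 2)
  moved <- toy$xyz %*% rot_z(37) + matrix(c(5, -3, 11), nrow(toy$xyz), 3, byrow = TRUE)
  ens <- new_ensemble(toy$atoms, rbind(allonet:::flat_xyz(toy$xyz),
                                       allonet:::flat_xyz(moved)))
  fit <- superpose_ensemble(ens, reference = 1)
  expect_lt(coord_rmsd(frame_coords(fit, 2), frame_coords(fit, 1)), 1e-8)
  # one-frame ensemble against itself is unchanged up to numerics
  one <- new_ensemble(toy$atoms, matrix(allonet:::flat_xyz(toy$xyz), 1))
  fit1 <- superpose_ensemble(one, reference = 1)
  expect_lt(max(abs(fit1$xyz - one$xyz)), 1e-8)
})

test_that("superposition never increases the fit RMSD and is idempotent", {
  toy <- build_toy_protein(6, "helix", 1, seed = 4)
  ens <- make_two_state_ensemble(toy, toy, 1, sigma = 0.5, n_frames = 4, seed = 5)
  pre <- coord_rmsd(frame_coords(ens, 2), frame_coords(ens, 1))
  fit <- superpose_ensemble(ens, reference = 1, atom_mode = "all")
  post <- coord_rmsd(frame_coords(fit, 2), frame_coords(fit, 1))
  expect_lte(post, pre + 1e-12)
  # exhaustive rotation-grid check on a 3-atom toy: no grid rotation beats Kabsch
  P <- matrix(c(0, 0, 0, 1.2, 0.1, 0, 0.3, 1.4, 0.2), 3, byrow = TRUE)
  Q <- matrix(c(0.1, 0, 0, 1.1, 0.4, 0, 0.2, 1.2, 0.5), 3, byrow = TRUE)
  k <- allonet:::kabsch(P, Q)
  best_k <- coord_rmsd(allonet:::apply_fit(P, k), Q)
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))) {
    for (deg in seq(0, 350, by = 10)) {
      R <- rot_axis(ax, deg)
      Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
      expect_gte(coord_rmsd(Pc %*% R, Qc), best_k - 1e-9)
    }
  }
  refit <- superpose_ensemble(fit, reference = 1, atom_mode = "all")
  expect_lt(max(abs(refit$xyz - fit$xyz)), 1e-8)
})

test_that("B-factors: zero for rigid ensembles, closed form for isotropic jitter", {
  toy <- build_toy_protein(5, "helix", 1, seed = 1)
  rigid <- make_two_state_ensemble(toy, toy, 1, sigma = 0, n_frames = 3, seed = 1)
  b <- bfactor_profile(rigid, "CA")
  expect_equal(b$bfactor, rep(0, 5))
  expect_warning(bfactor_profile(as_ensemble(toy)), "single-frame")
  jit <- make_two_state_ensemble(toy, toy, 1, sigma = sqrt(0.1), n_frames = 10000,
                                 seed = 6)
  bj <- bfactor_profile(jit, "CA")   # no superposition: jitter is the signal
  expect_equal(mean(bj$bfactor), 8 * pi^2 * 0.1, tolerance = 0.05)
  jit2 <- make_two_state_ensemble(toy, toy, 1, sigma = 2 * sqrt(0.1),
                                  n_frames = 10000, seed = 6)
  bj2 <- bfactor_profile(jit2, "CA")
  expect_equal(mean(bj2$bfactor) / mean(bj$bfactor), 4, tolerance = 0.05)
})

test_that("cross-correlation basics: unit diagonal, perfect co-movement", {
  toy <- build_toy_protein(4, "extended", 0, seed = 1)
  # all residues displaced by the same vector each frame -> C = 1
  base <- allonet:::flat_xyz(toy$xyz)
  shifts <- c(0, 0.5, -0.3, 0.8)
  xyz <- t(vapply(shifts, function(s) base + s, numeric(length(base))))
  ens <- new_ensemble(toy$atoms, xyz)
  C <- cross_correlation(ens)
  expect_equal(unname(unclass(C)), matrix(1, 4, 4), tolerance = 1e-12)
  expect_equal(unname(diag(C)), rep(1, 4))
})

test_that("zero-variance residues yield zero correlation with a warning", {
  toy <- build_toy_protein(4, "extended", 0, seed = 1)
  base <- allonet:::flat_xyz(toy$xyz)
  xyz <- rbind(base, base, base)
  xyz[2, 4] <- xyz[2, 4] + 1   # only residue 2 moves
  ens <- new_ensemble(toy$atoms, xyz)
  expect_warning(C <- cross_correlation(ens), "zero-variance")
  expect_equal(unname(C[1, 3]), 0)
  expect_equal(unname(diag(C)), rep(1, 4))
})

test_that("PCA finds a planted single direction and conserves variance", {
  toy <- build_toy_ca_trace(6, "extended")
  base <- allonet:::flat_xyz(toy$xyz)
  dir <- rep(0, length(base)); dir[1] <- 1; dir[4] <- -1
  dir <- dir / sqrt(sum(dir^2))
  amp <- seq(-1, 1, length.out = 9)
  ens <- new_ensemble(toy$atoms, t(vapply(amp, function(a) base + a * dir,
                                          numeric(length(base)))))
  p <- pca_modes(ens)
  expect_gt(abs(sum(p$vectors[, 1] * dir)), 0.999)
  expect_lt(p$values[2], 1e-10 * p$values[1])
  expect_equal(sum(p$values), p$trace, tolerance = 1e-8)
  expect_error(pca_modes(as_ensemble(toy)), class = "allonet_insufficient_data")
  # orthonormality of modes
  G <- crossprod(p$vectors[, 1:5])
  expect_lt(max(abs(G - diag(5))), 1e-8)
})

test_that("PCA top eigenvalue matches the ANM model on sampled data", {
  toy <- build_toy_ca_trace(10, "helix")
  m <- anm_covariance(toy)
  ens <- sample_gaussian_ensemble(m, 50000, seed = 13)
  p <- pca_modes(ens)
  lam_true <- max(eigen(m$covariance, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(p$values[1], lam_true, tolerance = 0.1)
})

test_that("mode mobility: completeness identity and planted-direction shape", {
  toy <- build_toy_ca_trace(8, "helix")
  m <- anm_covariance(toy)
  ens <- sample_gaussian_ensemble(m, 500, seed = 3)
  fit <- superpose_ensemble(ens)
  p <- pca_modes(fit)
  mob_all <- mode_mobility_profile(p, length(p$values))
  b <- bfactor_profile(fit, "CA")
  expect_equal(mob_all$mobility, sqrt(b$bfactor * 3 / (8 * pi^2) * nrow(fit$xyz) / (nrow(fit$xyz) - 1)),
               tolerance = 1e-8)
  expect_error(mode_mobility_profile(p, length(p$values) + 1),
               class = "allonet_parameter_error")
  # single planted direction: mobility proportional to |direction| per residue
  base <- allonet:::flat_xyz(toy$xyz)
  dir <- rep(0, length(base)); dir[c(1, 2, 7)] <- c(0.6, 0.8, 0.5)
  ens1 <- new_ensemble(toy$atoms, t(vapply(seq(-1, 1, length.out = 7),
                                           function(a) base + a * dir,
                                           numeric(length(base)))))
  p1 <- pca_modes(ens1)
  mob1 <- mode_mobility_profile(p1, 1)
  amp_res <- sqrt(c(0.6^2 + 0.8^2, 0, 0.5^2, rep(0, 5)))
  expect_equal(mob1$mobility / max(mob1$mobility), amp_res / max(amp_res),
               tolerance = 1e-6)
})

test_that("rigid-body decomposition recovers a constructed probe rotation", {
  fit_part <- build_toy_protein(6, "helix", 1, seed = 8)
  probe_part <- build_toy_protein(5, "extended", 1, seed = 9)
  probe_part$xyz <- probe_part$xyz + 30   # far away, separate chain block
  probe_part$atoms$resno <- probe_part$atoms$resno + 100
  atoms <- allonet:::make_atom_table(
    c(fit_part$atoms$elety, probe_part$atoms$elety),
    c(fit_part$atoms$element, probe_part$atoms$element),
    "A", c(fit_part$atoms$resno, probe_part$atoms$resno), "",
    c(fit_part$atoms$resid, probe_part$atoms$resid))
  xyz0 <- rbind(fit_part$xyz, probe_part$xyz)
  cen <- colMeans(probe_part$xyz)
  rot <- sweep(sweep(probe_part$xyz, 2, cen) %*% rot_z(30), 2, cen, `+`)
  xyz1 <- rbind(fit_part$xyz, rot)
  ens <- new_ensemble(atoms, rbind(allonet:::flat_xyz(xyz0), allonet:::flat_xyz(xyz1)))
  rb <- rigid_body_decomposition(ens, 1:6, 7:11, reference = 1, atom_mode = "all")
  expect_equal(rb$rmsd[1], 0, tolerance = 1e-9)
  expect_equal(rb$angle[1], 0, tolerance = 1e-5)
  expect_equal(rb$angle[2], 30, tolerance = 1e-6)
  # RMSD invariant to a global rotation of the whole frame
  glob <- xyz1 %*% rot_z(55) + matrix(c(1, 2, 3), nrow(xyz1), 3, byrow = TRUE)
  ens2 <- new_ensemble(atoms, rbind(allonet:::flat_xyz(xyz0), allonet:::flat_xyz(glob)))
  rb2 <- rigid_body_decomposition(ens2, 1:6, 7:11, reference = 1, atom_mode = "all")
  expect_equal(rb2$rmsd[2], rb$rmsd[2], tolerance = 1e-8)
  expect_equal(rb2$angle[2], 30, tolerance = 1e-4)
})

test_that("density of states: conservation, degenerate input, two-state recovery", {
  d0 <- density_of_states(rep(1, 50), rep(2, 50), bins = 20)
  expect_equal(sum(d0$counts), 50)
  expect_equal(nrow(d0$peaks), 1L)
  expect_equal(d0$peaks$fraction, 1.0)
  expect_error(density_of_states(1:5, 1:4), class = "allonet_consistency_error")

  set.seed(42)
  n <- 2000
  lab <- stats::runif(n) < 0.7
  energy <- ifelse(lab, -100, -80) + stats::rnorm(n, sd = 2)
  rmsd <- ifelse(lab, 1, 6) + stats::rnorm(n, sd = 0.3)
  d <- density_of_states(energy, rmsd, bins = 40)
  expect_equal(sum(d$counts), n)
  expect_gte(nrow(d$peaks), 2L)
  expect_lt(abs(d$peaks$fraction[1] - 0.7), 3 * sqrt(0.7 * 0.3 / n) + 0.02)
})

test_that("profiles are invariant to a uniform global rigid-body motion", {
  toy <- build_toy_ca_trace(8, "helix")
  m <- anm_covariance(toy)
  ens <- sample_gaussian_ensemble(m, 300, seed = 17)
  R <- rot_z(63); tvec <- c(4, -2, 9)
  moved <- t(apply(ens$xyz, 1, function(fr) {
    co <- matrix(fr, ncol = 3, byrow = TRUE)
    allonet:::flat_xyz(co %*% R + matrix(tvec, nrow(co), 3, byrow = TRUE))
  }))
  ens2 <- new_ensemble(ens$atoms, moved)
  f1 <- superpose_ensemble(ens); f2 <- superpose_ensemble(ens2)
  expect_equal(bfactor_profile(f1, "CA")$bfactor, bfactor_profile(f2, "CA")$bfactor,
               tolerance = 1e-6)
  expect_equal(unclass(cross_correlation(f1)), unclass(cross_correlation(f2)),
               tolerance = 1e-6)
})
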
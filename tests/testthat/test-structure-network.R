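# Contact counting, normalization, Eq-3 strengths, thresholded graphs,
# largest-cluster scan, and ensemble graph persistence.

# Hand-placed two-residue fixture: side chains engineered so exactly
# `n_close` CB/CG atom pairs fall within 4.5 A.
two_residue_fixture <- function(gap = 20) {
  elety <- rep(c("N", "CA", "CB", "CG"), 2)
  resno <- rep(1:2, each = 4)
  atoms <- allonet:::make_atom_table(elety, substr(elety, 1, 1), "A", resno, "",
                                     rep(c("VAL", "LEU"), each = 4))
  xyz <- rbind(
    c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),        # residue 1
    c(gap + 1, 0, 0), c(gap, 0, 0), c(gap - 4, 0, 0), c(gap - 5, 0, 0))
  new_structure(atoms, xyz)
}

test_that("contact counts match brute force and obey the conventions", {
  # residues 30 A apart -> no contacts
  far <- two_residue_fixture(gap = 34)
  expect_equal(atom_contact_counts(far, 1, 2), 0L)
  # residues at resno 1,3 (non-adjacent) with engineered pair count
  s <- two_residue_fixture(gap = 10)
  s$atoms$resno[s$atoms$res_index == 2] <- 3L
  s$atoms$residue_key <- paste(s$atoms$chain, s$atoms$resno, s$atoms$insert, sep = ":")
  # sidechain atoms: res1 {CB@1, CG@2}, res2 {CB@6, CG@5}
  # distances: 1-6: 5, 1-5: 4, 2-6: 4, 2-5: 3  -> 3 pairs <= 4.5
  expect_equal(atom_contact_counts(s, 1, 2), 3L)
  expect_equal(atom_contact_counts(s, 1, 2), brute_contacts(s, 1, 2))
  # sequence neighbours are 0 regardless of geometry
  adj <- two_residue_fixture(gap = 3)
  expect_equal(atom_contact_counts(adj, 1, 2), 0L)
  # randomized toys against the brute-force double loop
  toy <- build_toy_protein(12, "helix", 3, seed = 5)
  for (i in c(1, 3, 6)) for (j in c(5, 8, 12)) {
    if (i == j) next
    expect_equal(atom_contact_counts(toy, i, j), brute_contacts(toy, i, j),
                 info = sprintf("pair %d-%d", i, j))
  }
})

test_that("interaction matrix equals brute-force counts on a toy protein", {
  toy <- build_toy_protein(10, "helix", 3, seed = 2)
  norm <- suppressMessages(derive_normalization_table(toy))
  im <- interaction_strengths(toy, norm)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(im$n[i, j], brute_contacts(toy, i, j),
                 info = sprintf("pair %d-%d", i, j))
  }
  expect_true(isSymmetric(im$n))
  expect_true(all(diag(im$I) == 0))
})

test_that("Eq-3 evaluation: product and sqrt denominators", {
  s <- two_residue_fixture(gap = 10)
  s$atoms$resno[s$atoms$res_index == 2] <- 3L
  s$atoms$residue_key <- paste(s$atoms$chain, s$atoms$resno, s$atoms$insert, sep = ":")
  norm <- structure(c(VAL = 10, LEU = 10), class = "normalization_table")
  # engineered n_12 = 3; force n = 4 with a wider fixture for the worked case
  im <- interaction_strengths(s, norm)
  expect_equal(im$n[1, 2], 3L)
  expect_equal(im$I[1, 2], 3 / (10 * 10) * 100)
  im_s <- interaction_strengths(s, norm, denominator = "sqrt_product")
  expect_equal(im_s$I[1, 2], 3 / 10 * 100)
  # the worked 4-pair example: n=4, N_i=N_j=10 -> 4.0% (product), 40% (sqrt)
  s4 <- s
  s4$xyz[7, ] <- c(5.5, 0, 0)   # CB of residue 2: 4.5 A from CB1 (inclusive)
  s4$xyz[8, ] <- c(4.0, 0, 0)   # CG of residue 2: within range of both
  n4 <- atom_contact_counts(s4, 1, 2)
  expect_equal(n4, 4L)
  im4 <- interaction_strengths(s4, norm)
  expect_equal(im4$I[1, 2], 4.0)
  im4s <- interaction_strengths(s4, norm, denominator = "sqrt_product")
  expect_equal(im4s$I[1, 2], 40.0)
  # zero contacts -> zero strength
  imf <- interaction_strengths(two_residue_fixture(gap = 34), norm)
  expect_equal(imf$I[1, 2], 0)
})

test_that("normalization table: data-derived max, override, coverage error", {
  toy <- build_toy_protein(10, "helix", 2, seed = 3)
  expect_message(norm <- derive_normalization_table(toy), "normalization table")
  # N_i is the max per-type total pair count, verified brute force
  a <- toy$atoms
  heavy <- which(a$is_heavy)
  per_res <- vapply(seq_len(10), function(r) {
    cnt <- 0L
    for (p in heavy[a$res_index[heavy] == r]) for (q in heavy[a$res_index[heavy] != r])
      if (sqrt(sum((toy$xyz[p, ] - toy$xyz[q, ])^2)) <= 4.5) cnt <- cnt + 1L
    cnt
  }, integer(1))
  rt <- residue_table(toy)
  for (ty in unique(rt$resid))
    expect_equal(unname(norm[ty]), max(1, max(per_res[rt$resid == ty])),
                 info = ty)
  # override wins
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("restype\tN", "ALA\t7", "VAL\t9"), tf)
  ov <- derive_normalization_table(toy, override = tf)
  expect_equal(unname(ov["ALA"]), 7)
  # missing residue type at evaluation time -> coverage error
  expect_error(interaction_strengths(toy, ov), class = "allonet_coverage_error")
  expect_error(derive_normalization_table(list()), class = "allonet_coverage_error")
})

test_that("graphs are nested under increasing I_min and edge rule is inclusive", {
  toy <- build_toy_protein(15, "helix", 3, seed = 4)
  norm <- suppressMessages(derive_normalization_table(toy))
  im <- interaction_strengths(toy, norm, "sqrt_product")
  g0 <- build_graph(im, 0)
  expect_equal(igraph::ecount(g0), sum(im$I > 0 & upper.tri(im$I)))
  vals <- im$I[im$I > 0 & upper.tri(im$I)]
  thr <- sort(vals)[ceiling(length(vals) / 2)]   # an attained strength
  g_at <- build_graph(im, thr)   # inclusive threshold keeps edges == thr
  expect_true(any(abs(igraph::E(g_at)$I - thr) < 1e-12))
  g_hi <- build_graph(im, max(im$I) + 1)
  expect_equal(igraph::ecount(g_hi), 0L)
  e2 <- igraph::as_edgelist(build_graph(im, 2))
  e5 <- igraph::as_edgelist(build_graph(im, 5))
  key <- function(el) paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  expect_true(all(key(e5) %in% key(e2)))
})

test_that("largest-cluster transition scan finds the engineered collapse", {
  # complete 6-node graph with all I_ij equal: single cliff at that value
  keys <- paste0("A:", 1:6, ":")
  I <- matrix(3, 6, 6, dimnames = list(keys, keys)); diag(I) <- 0
  n <- matrix(1L, 6, 6); diag(n) <- 0L
  im <- structure(list(I = I, n = n, cutoff = 4.5, denominator = "product"),
                  class = "interaction_matrix")
  sc <- lcc_transition_scan(im, grid = 1:15)
  expect_equal(sc$transition, 4)   # first grid point past I = 3
  expect_equal(sc$scan$lcc_size[sc$scan$I_min <= 3], rep(6, 3))
  expect_equal(sc$scan$lcc_size[sc$scan$I_min > 3], rep(1, 12))
  # dense toy collapsing between 2 and 3 percent
  I2 <- I; I2[] <- 0
  for (i in 1:5) { I2[i, i + 1] <- I2[i + 1, i] <- 2.5 }
  I2[1, 3] <- I2[3, 1] <- 8
  im2 <- structure(list(I = I2, n = n, cutoff = 4.5, denominator = "product"),
                   class = "interaction_matrix")
  sc2 <- lcc_transition_scan(im2, grid = 1:15)
  expect_equal(sc2$transition, 3)
  # empty matrix: flat curve -> undefined transition
  I3 <- I; I3[] <- 0
  im3 <- structure(list(I = I3, n = n, cutoff = 4.5, denominator = "product"),
                   class = "interaction_matrix")
  expect_warning(sc3 <- lcc_transition_scan(im3), "flat")
  expect_true(is.na(sc3$transition))
})

test_that("ensemble graphs: persistence equals exact recount; stride works", {
  toy <- build_toy_protein(10, "helix", 3, seed = 6)
  ens <- make_two_state_ensemble(toy, toy, 1, sigma = 0.35, n_frames = 20, seed = 7)
  norm <- suppressMessages(derive_normalization_table(toy))
  egs <- ensemble_graphs(ens, norm, I_min = 1, denominator = "sqrt_product")
  expect_equal(egs$n_snapshots, 20L)
  # brute-force recount of every edge's persistence
  for (r in seq_len(nrow(egs$persistence))) {
    a <- egs$persistence$resA[r]; b <- egs$persistence$resB[r]
    cnt <- sum(vapply(egs$graphs, function(g)
      igraph::are_adjacent(g, a, b), logical(1)))
    expect_equal(egs$persistence$fraction[r], cnt / 20)
  }
  expect_true(all(egs$persistence$fraction >= 0 & egs$persistence$fraction <= 1))
  # rigid ensemble: every edge persists fully
  rigid <- make_two_state_ensemble(toy, toy, 1, sigma = 0, n_frames = 5, seed = 8)
  egr <- ensemble_graphs(rigid, norm, I_min = 1, denominator = "sqrt_product")
  expect_true(all(egr$persistence$fraction == 1))
  # stride halves the snapshot count
  eg2 <- ensemble_graphs(ens, norm, I_min = 1, stride = 2,
                         denominator = "sqrt_product")
  expect_equal(eg2$n_snapshots, 10L)
})
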
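#' Side-chain atom contact count between two residues
#'
#' Number of distinct heavy side-chain atom pairs of residues i and j within
#' \code{cutoff} (inclusive).  Sequence-adjacent residues return 0 by
#' convention: non-covalent interactions between sequence neighbours are
#' ignored in graph construction.  Glycine's "side chain" is its C-alpha.
#'
#' @param structure a `Structure`
#' @param i,j residue keys or indices
#' @param cutoff contact distance (Angstrom, default 4.5)
#' @return integer pair count
#' @export
atom_contact_counts <- function(structure, i, j, cutoff = 4.5) {
  ri <- resolve_residues(structure, i); rj <- resolve_residues(structure, j)
  if (ri == rj) stop_allonet("i and j must differ", "allonet_parameter_error")
  atoms <- structure$atoms
  rt <- residue_table(structure)
  if (rt$chain[ri] == rt$chain[rj] && abs(rt$resno[ri] - rt$resno[rj]) == 1)
    return(0L)
  sc <- sidechain_atom_indices(atoms)
  ai <- sc[atoms$res_index[sc] == ri]; aj <- sc[atoms$res_index[sc] == rj]
  if (!length(ai) || !length(aj)) return(0L)
  d2 <- outer(seq_along(ai), seq_along(aj), function(p, q)
    rowSums((structure$xyz[ai[p], , drop = FALSE] -
             structure$xyz[aj[q], , drop = FALSE])^2))
  sum(d2 <= cutoff^2)
}

#' Derive side-chain size normalization factors
#'
#' For every residue instance, the total number of heavy-atom interaction
#' pairs it makes (main-chain and side-chain atoms against all atoms of
#' other residues within \code{cutoff}); \eqn{N_i} for a residue type is the
#' chosen percentile (default: maximum) over its instances.  A user-supplied
#' table overrides the data-derived values.
#'
#' @param structures a `Structure` or list of structures
#' @param cutoff contact distance (Angstrom)
#' @param percentile percentile in (0, 100]; 100 = maximum
#' @param override optional named numeric vector or 2-column table file
#'   (restype, N) taking precedence
#' @return named numeric vector of class `normalization_table`
#' @export
derive_normalization_table <- function(structures, cutoff = 4.5, percentile = 100,
                                       override = NULL) {
  if (!is.null(override)) {
    if (is.character(override)) {
      tab <- utils::read.table(override, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      override <- stats::setNames(as.numeric(tab[[2]]), tab[[1]])
    }
    if (any(override <= 0))
      stop_allonet("normalization factors must be positive", "allonet_validation_error")
    return(structure(override, class = "normalization_table"))
  }
  if (inherits(structures, "Structure")) structures <- list(structures)
  if (!length(structures))
    stop_allonet("no structures to derive normalization from", "allonet_coverage_error")
  counts <- numeric(0); types <- character(0)
  for (s in structures) {
    atoms <- s$atoms
    heavy <- which(atoms$is_heavy)
    co <- s$xyz[heavy, , drop = FALSE]
    D <- as.matrix(stats::dist(co))
    res_h <- atoms$res_index[heavy]
    within <- D <= cutoff & outer(res_h, res_h, `!=`)
    per_atom <- rowSums(within)
    per_res <- tapply(per_atom, res_h, sum)   # pairs counted once per residue
    rt <- residue_table(s)
    counts <- c(counts, as.numeric(per_res))
    types <- c(types, rt$resid[match(as.integer(names(per_res)), rt$res_index)])
  }
  n_i <- tapply(counts, types, function(x)
    if (percentile >= 100) max(x) else stats::quantile(x, percentile / 100, names = FALSE))
  n_i <- pmax(as.numeric(n_i), 1)   # floor at 1 so I_ij stays defined
  out <- stats::setNames(n_i, names(tapply(counts, types, max)))
  message("normalization table derived from input structures: ",
          paste(sprintf("%s=%g", names(out), out), collapse = ", "))
  structure(out, class = "normalization_table")
}

#' Normalized residue interaction strengths
#'
#' \eqn{I_{ij} = n_{ij} / (N_i \times N_j) \times 100} (percent), where
#' \eqn{n_{ij}} counts side-chain heavy-atom contacts within \code{cutoff}.
#' The printed product denominator is the default; the
#' \code{"sqrt_product"} variant \eqn{n_{ij}/\sqrt{N_i N_j} \times 100}
#' common in the protein structure network literature is available as a
#' switch.
#'
#' @param structure a `Structure`
#' @param norm a `normalization_table` (see [derive_normalization_table()])
#' @param denominator "product" or "sqrt_product"
#' @param cutoff contact distance (Angstrom)
#' @return object of class `interaction_matrix`: percent matrix `I`, raw
#'   counts `n`, cutoff and denominator used
#' @export
interaction_strengths <- function(structure, norm,
                                  denominator = c("product", "sqrt_product"),
                                  cutoff = 4.5) {
  denominator <- match.arg(denominator)
  atoms <- structure$atoms
  rt <- residue_table(structure)
  missing_types <- setdiff(unique(rt$resid), names(norm))
  if (length(missing_types))
    stop_allonet(paste("no normalization factor for residue type(s):",
                       paste(missing_types, collapse = ", ")),
                 "allonet_coverage_error")
  sc <- sidechain_atom_indices(atoms)
  co <- structure$xyz[sc, , drop = FALSE]
  res_sc <- atoms$res_index[sc]
  D2 <- as.matrix(stats::dist(co))^2
  nres <- nrow(rt)
  nmat <- matrix(0L, nres, nres)
  hit <- which(D2 <= cutoff^2 & upper.tri(D2), arr.ind = TRUE)
  if (nrow(hit)) {
    ri <- res_sc[hit[, 1]]; rj <- res_sc[hit[, 2]]
    ok <- ri != rj
    for (k in which(ok)) {
      a <- ri[k]; b <- rj[k]
      nmat[a, b] <- nmat[a, b] + 1L
    }
    nmat <- nmat + t(nmat)
  }
  # exclude sequence neighbours
  adj <- outer(rt$chain, rt$chain, `==`) & abs(outer(rt$resno, rt$resno, `-`)) == 1
  nmat[adj] <- 0L
  diag(nmat) <- 0L
  Ni <- as.numeric(norm[rt$resid])
  den <- if (denominator == "product") outer(Ni, Ni) else sqrt(outer(Ni, Ni))
  I <- nmat / den * 100
  dimnames(I) <- list(rt$residue_key, rt$residue_key)
  dimnames(nmat) <- dimnames(I)
  structure(list(I = I, n = nmat, cutoff = cutoff, denominator = denominator,
                 norm = norm),
            class = "interaction_matrix")
}

#' Build a residue interaction graph at a threshold
#'
#' Residues i and j are connected iff \eqn{I_{ij} \ge I_{min}} (inclusive)
#' and \eqn{I_{ij} > 0}.
#'
#' @param im an `interaction_matrix`
#' @param I_min edge inclusion threshold in percent (default 2.5)
#' @return an igraph over all residues, with edge attributes `I` and `n` and
#'   graph attribute `I_min`
#' @export
build_graph <- function(im, I_min = 2.5) {
  if (I_min < 0) stop_allonet("I_min must be >= 0", "allonet_parameter_error")
  A <- (im$I >= I_min & im$I > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el)) {
    igraph::E(g)$I <- im$I[el]
    igraph::E(g)$n <- im$n[el]
  }
  igraph::set_graph_attr(g, "I_min", I_min)
}

#' Largest-connected-cluster transition scan over I_min
#'
#' Computes the largest connected component size on a grid of I_min values
#' and reports the transition point: the grid value with the steepest
#' decrease of the largest-cluster size (maximum backward difference), ties
#' resolved towards the smaller I_min.
#'
#' @param im an `interaction_matrix`
#' @param grid ascending I_min values in percent (default 1..15)
#' @return list: `scan` data.frame (I_min, lcc_size), `transition` (I_min or
#'   NA when the curve is flat)
#' @export
lcc_transition_scan <- function(im, grid = 1:15) {
  if (is.unsorted(grid)) stop_allonet("grid must be ascending", "allonet_parameter_error")
  sizes <- vapply(grid, function(t) {
    g <- build_graph(im, t)
    max(igraph::components(g)$csize)
  }, numeric(1))
  drop <- c(0, -diff(sizes))
  if (all(drop <= 0)) {
    warning("flat largest-cluster curve: transition undefined")
    trans <- NA_real_
  } else trans <- grid[which.max(drop)]
  list(scan = data.frame(I_min = grid, lcc_size = sizes), transition = trans)
}

#' Per-snapshot residue graphs with edge persistence
#'
#' Builds the interaction graph for (up to \code{max_snapshots}) frames of
#' an ensemble and records, for every edge observed anywhere, the fraction
#' of selected snapshots that contain it.
#'
#' @param ensemble a `StructuralEnsemble`
#' @param norm a `normalization_table`
#' @param I_min edge threshold (percent)
#' @param max_snapshots cap on the number of snapshots analysed
#' @param stride frame stride (default: chosen so the cap is respected)
#' @param denominator,cutoff passed to [interaction_strengths()]
#' @return object of class `ensemble_graphs`: list of igraphs, persistence
#'   data.frame (resA, resB, fraction), snapshot count, node names
#' @export
ensemble_graphs <- function(ensemble, norm, I_min = 2.5, max_snapshots = 1000L,
                            stride = NULL,
                            denominator = c("product", "sqrt_product"),
                            cutoff = 4.5) {
  denominator <- match.arg(denominator)
  F <- n_frames(ensemble)
  stride <- stride %||% max(1L, ceiling(F / max_snapshots))
  sel <- seq(1L, F, by = stride)
  if (length(sel) > max_snapshots) sel <- sel[seq_len(max_snapshots)]
  graphs <- lapply(sel, function(f)
    build_graph(interaction_strengths(frame_structure(ensemble, f), norm,
                                      denominator, cutoff), I_min))
  edge_keys <- lapply(graphs, function(g) {
    el <- igraph::as_edgelist(g)
    if (!nrow(el)) character(0) else paste(pmin(el[, 1], el[, 2]),
                                           pmax(el[, 1], el[, 2]), sep = "\r")
  })
  all_keys <- unique(unlist(edge_keys))
  frac <- if (length(all_keys)) {
    tab <- table(factor(unlist(edge_keys), levels = all_keys))
    as.numeric(tab) / length(graphs)
  } else numeric(0)
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  persistence <- data.frame(
    resA = vapply(parts, `[`, "", 1), resB = vapply(parts, `[`, "", 2),
    fraction = frac, stringsAsFactors = FALSE)
  structure(list(graphs = graphs, persistence = persistence,
                 n_snapshots = length(graphs), frames = sel,
                 nodes = igraph::V(graphs[[1]])$name, I_min = I_min),
            class = "ensemble_graphs")
}
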
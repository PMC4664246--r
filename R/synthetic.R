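#' Two-state conformational mixture ensemble
#'
#' Each frame is drawn from conformer A with probability \code{p_A} and from
#' conformer B otherwise, plus isotropic per-coordinate Gaussian noise of
#' standard deviation \code{sigma}; the true generating state of every frame
#' is recorded in \code{labels}.  This emulates a population-shift ensemble
#' with known state populations.
#'
#' @param conformer_a,conformer_b `Structure`s sharing one topology
#' @param p_a population of state A in [0, 1]
#' @param sigma isotropic per-coordinate noise sd (Angstrom)
#' @param n_frames number of frames
#' @param seed RNG seed
#' @return a labeled [new_ensemble()]
#' @export
make_two_state_ensemble <- function(conformer_a, conformer_b, p_a, sigma = 0.2,
                                    n_frames = 1000L, seed = 1L) {
  if (p_a < 0 || p_a > 1) stop_allonet("p_a must be in [0,1]", "allonet_parameter_error")
  if (sigma < 0) stop_allonet("sigma must be >= 0", "allonet_parameter_error")
  if (!identical(conformer_a$atoms[c("elety", "chain", "resno", "insert")],
                 conformer_b$atoms[c("elety", "chain", "resno", "insert")]))
    stop_allonet("conformers must share one topology", "allonet_consistency_error")
  xa <- flat_xyz(conformer_a$xyz); xb <- flat_xyz(conformer_b$xyz)
  with_op_seed(seed, "make_two_state_ensemble", {
    is_a <- stats::runif(n_frames) < p_a
    xyz <- matrix(xb, n_frames, length(xb), byrow = TRUE)
    if (any(is_a)) xyz[is_a, ] <- matrix(xa, sum(is_a), length(xa), byrow = TRUE)
    if (sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = sigma), n_frames)
    new_ensemble(conformer_a$atoms, xyz, labels = ifelse(is_a, "A", "B"))
  })
}

#' Random graph with planted communities
#'
#' Nodes inside each planted block are connected with probability
#' \code{intra_p}, nodes of different blocks with probability \code{inter_p}.
#' The planted blocks are attached as the graph attribute \code{planted}.
#'
#' @param blocks list of character/integer node sets (may overlap)
#' @param intra_p,inter_p edge probabilities in [0, 1]
#' @param extra_nodes nodes belonging to no block
#' @param seed RNG seed
#' @return an igraph with vertex names and attribute `planted`
#' @export
planted_community_graph <- function(blocks, intra_p = 1, inter_p = 0,
                                    extra_nodes = character(), seed = 1L) {
  if (intra_p < 0 || intra_p > 1 || inter_p < 0 || inter_p > 1)
    stop_allonet("probabilities must be in [0,1]", "allonet_parameter_error")
  blocks <- lapply(blocks, as.character)
  nodes <- unique(c(unlist(blocks), as.character(extra_nodes)))
  same_block <- function(a, b)
    any(vapply(blocks, function(bl) a %in% bl && b %in% bl, logical(1)))
  with_op_seed(seed, "planted_community_graph", {
    edges <- character(0)
    n <- length(nodes)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      p <- if (same_block(nodes[i], nodes[j])) intra_p else inter_p
      if (stats::runif(1) < p) edges <- c(edges, nodes[i], nodes[j])
    }
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    if (length(edges)) g <- igraph::add_edges(g, match(edges, nodes))
    g <- igraph::set_graph_attr(g, "planted", blocks)
    g
  })
}

#' Synthetic per-snapshot energy table
#'
#' Gaussian per-frame energy terms with prescribed means and standard
#' deviations; a fixture with known aggregates for the MM-GBSA bookkeeping.
#'
#' @param n_frames rows
#' @param term_means named numeric vector (e.g. dE_vdw, dE_elec, dG_np,
#'   dG_elec_solv, dE_intra)
#' @param term_sds standard deviations, same names (default all 0)
#' @param seed RNG seed
#' @return a `snapshot_energy_table` data.frame
#' @export
synthetic_energy_table <- function(n_frames, term_means,
                                   term_sds = stats::setNames(rep(0, length(term_means)),
                                                              names(term_means)),
                                   seed = 1L) {
  if (is.null(names(term_means)) || any(!nzchar(names(term_means))))
    stop_allonet("term_means must be named", "allonet_parameter_error")
  term_sds <- term_sds[names(term_means)]
  if (anyNA(term_sds) || any(term_sds < 0))
    stop_allonet("term_sds must be non-negative, one per term", "allonet_parameter_error")
  with_op_seed(seed, "synthetic_energy_table", {
    out <- as.data.frame(lapply(seq_along(term_means), function(k)
      term_means[[k]] + stats::rnorm(n_frames, sd = term_sds[[k]])))
    names(out) <- names(term_means)
    out <- cbind(frame = seq_len(n_frames), out)
    class(out) <- c("snapshot_energy_table", "data.frame")
    out
  })
}
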
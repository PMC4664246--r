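#' Dynamics-weighted edges for shortest-path analysis
#'
#' Edge weights convert correlation into an information-flow distance,
#' \eqn{w_{ij} = -\log |C_{ij}|}; perfectly correlated residues are at
#' distance 0.  \eqn{|C|} is floored at \code{floor} so weights stay finite.
#' When \code{c_min} is set (default 0.5, the correlated-intermediates band)
#' edges with \eqn{|C_{ij}| < c_{min}} are removed before pathfinding, which
#' is equivalent to requiring every consecutive residue pair along a path to
#' be correlated.  Set \code{signed = TRUE} to apply \code{c_min} to the
#' signed correlation instead (excluding strong anti-correlations).
#'
#' @param graph an igraph residue graph (from [build_graph()] or any graph
#'   with vertex names)
#' @param C a `CrossCorrelationMatrix` covering all graph nodes
#' @param floor lower bound on |C| before taking the log
#' @param c_min correlation filter threshold, or NULL to keep all edges
#' @param signed apply `c_min` to signed C rather than |C|
#' @return the graph with a `weight` edge attribute
#' @export
assign_edge_weights <- function(graph, C, floor = 1e-8, c_min = 0.5,
                                signed = FALSE) {
  nodes <- igraph::V(graph)$name
  if (!all(nodes %in% rownames(C)))
    stop_allonet("correlation matrix does not cover all graph nodes",
                 "allonet_coverage_error")
  el <- igraph::as_edgelist(graph)
  if (nrow(el)) {
    cij <- C[cbind(el[, 1], el[, 2])]
    if (!is.null(c_min)) {
      keep <- if (signed) cij >= c_min else abs(cij) >= c_min
      graph <- igraph::delete_edges(graph, which(!keep))
      el <- el[keep, , drop = FALSE]
      cij <- cij[keep]
    }
    igraph::E(graph)$weight <- -log(pmax(abs(cij), floor))
  }
  graph
}

#' All-pairs shortest-path distances and multiplicities (Floyd-Warshall)
#'
#' Dense Floyd-Warshall with shortest-path counting: alongside the distance
#' matrix it tracks \eqn{g_{jk}}, the number of distinct shortest paths per
#' pair.  Two path lengths are considered equal when they differ by at most
#' \code{tol} relative, the explicit tie rule needed for multiplicity
#' counting on real-valued weights.
#'
#' @param graph igraph with non-negative edge `weight`s (unweighted graphs
#'   get unit weights)
#' @param tol relative tie tolerance
#' @return object of class `path_counts`: `dist`, `counts`, `nodes`, `tol`
#' @export
shortest_path_counts <- function(graph, tol = 1e-9) {
  n <- igraph::vcount(graph)
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(n))
  w <- if ("weight" %in% igraph::edge_attr_names(graph))
    igraph::E(graph)$weight else rep(1, igraph::ecount(graph))
  if (any(w < 0)) stop_allonet("negative weights not allowed", "allonet_parameter_error")
  d <- matrix(Inf, n, n); diag(d) <- 0
  g <- matrix(0, n, n)
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el)) {
    for (e in seq_len(nrow(el))) {
      i <- el[e, 1]; j <- el[e, 2]
      if (w[e] < d[i, j] - tol) { d[i, j] <- d[j, i] <- w[e]; g[i, j] <- g[j, i] <- 1 }
      else if (abs(w[e] - d[i, j]) <= tol * max(abs(w[e]), 1))  # parallel edge
        { g[i, j] <- g[i, j] + 1; g[j, i] <- g[i, j] }
    }
  }
  for (k in seq_len(n)) {
    dk <- d[, k]
    if (all(!is.finite(dk[-k]))) next
    alt <- outer(dk, d[k, ], `+`)
    cnt <- outer(g[, k], g[k, ])
    fin <- is.finite(alt)
    lt <- fin & alt < d - tol * pmax(abs(alt), 1)
    eq <- fin & !lt & abs(alt - d) <= tol * pmax(abs(alt), 1)
    lt[k, ] <- lt[, k] <- FALSE; eq[k, ] <- eq[, k] <- FALSE
    diag(lt) <- diag(eq) <- FALSE
    d[lt] <- alt[lt]; g[lt] <- cnt[lt]
    g[eq] <- g[eq] + cnt[eq]
  }
  structure(list(dist = d, counts = g, nodes = nodes, tol = tol),
            class = "path_counts")
}

#' Normalized betweenness centrality from path counts
#'
#' \eqn{C_b(i) = \sum_{j<k,\, j \ne i \ne k} g_{jk}(i)/g_{jk}}, normalized
#' per connected component by \eqn{(N-1)(N-2)/2} with N the size of i's
#' component, so \eqn{C_b \in [0,1]} and leaves score 0.  Components of
#' fewer than 3 nodes get centrality 0.
#'
#' @param counts a `path_counts` object
#' @return data.frame of class `centrality_profile`: node, betweenness,
#'   component size
#' @export
betweenness_profile <- function(counts) {
  d <- counts$dist; g <- counts$counts; n <- nrow(d)
  tol <- counts$tol
  comp_id <- integer(n); cid <- 0L
  for (i in seq_len(n)) if (!comp_id[i]) {
    cid <- cid + 1L
    comp_id[is.finite(d[i, ])] <- cid
  }
  comp_size <- as.numeric(table(comp_id))[comp_id]
  bw <- numeric(n)
  for (i in seq_len(n)) {
    if (comp_size[i] < 3) next
    alt <- outer(d[, i], d[i, ], `+`)
    on_path <- is.finite(alt) & abs(alt - d) <= tol * pmax(abs(alt), 1)
    through <- outer(g[, i], g[i, ])
    frac <- matrix(0, n, n)
    ok <- on_path & g > 0
    frac[ok] <- through[ok] / g[ok]
    frac[i, ] <- frac[, i] <- 0
    diag(frac) <- 0
    N <- comp_size[i]
    bw[i] <- sum(frac[upper.tri(frac)]) / ((N - 1) * (N - 2) / 2)
  }
  out <- data.frame(node = counts$nodes, betweenness = bw,
                    component_size = comp_size, stringsAsFactors = FALSE)
  class(out) <- c("centrality_profile", "data.frame")
  out
}

#' Betweenness of a graph in one call
#' @param graph igraph (optionally weighted)
#' @param tol tie tolerance, see [shortest_path_counts()]
#' @export
graph_betweenness <- function(graph, tol = 1e-9) {
  betweenness_profile(shortest_path_counts(graph, tol))
}

#' Ensemble-averaged betweenness centrality
#'
#' Per-residue mean of per-snapshot normalized betweenness over an ensemble
#' graph set, optionally with dynamics weights from a correlation matrix.
#'
#' @param egs an `ensemble_graphs` object
#' @param C optional `CrossCorrelationMatrix` for [assign_edge_weights()]
#' @param floor,c_min,signed passed to [assign_edge_weights()]
#' @return `centrality_profile` data.frame with the per-snapshot mean (and
#'   sd) of betweenness
#' @export
ensemble_centrality <- function(egs, C = NULL, floor = 1e-8, c_min = 0.5,
                                signed = FALSE) {
  profs <- lapply(egs$graphs, function(g) {
    if (!is.null(C)) g <- assign_edge_weights(g, C, floor, c_min, signed)
    graph_betweenness(g)
  })
  m <- vapply(profs, function(p) p$betweenness, numeric(length(egs$nodes)))
  m <- matrix(m, nrow = length(egs$nodes))
  out <- data.frame(node = egs$nodes, betweenness = rowMeans(m),
                    sd = apply(m, 1, stats::sd), stringsAsFactors = FALSE)
  class(out) <- c("centrality_profile", "data.frame")
  out
}

#' Probability distribution of residue centralities
#'
#' @param profile a `centrality_profile`
#' @param bins number of histogram bins over [0, max]
#' @param tail_quantile report the probability mass above this quantile of
#'   the centrality values
#' @return data.frame (bin_mid, prob) with attributes `tail_mass` and
#'   `tail_cut`
#' @export
centrality_distribution <- function(profile, bins = 25L, tail_quantile = 0.9) {
  v <- profile$betweenness
  if (!length(v)) stop_allonet("empty profile", "allonet_validation_error")
  hi <- max(v, 1e-12)
  edges <- seq(0, hi * (1 + 1e-9), length.out = bins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  prob <- tabulate(bin, nbins = bins) / length(v)
  cut <- stats::quantile(v, tail_quantile, names = FALSE)
  out <- data.frame(bin_mid = (edges[-1] + edges[-length(edges)]) / 2, prob = prob)
  attr(out, "tail_mass") <- mean(v > cut)
  attr(out, "tail_cut") <- cut
  out
}

#' Average centrality over named residue clusters
#'
#' Mean betweenness over each named set of residues (e.g. mutation
#' clusters).
#'
#' @param profile a `centrality_profile`
#' @param clusters named list of node-name vectors
#' @return data.frame: cluster, n, mean_betweenness
#' @export
cluster_average_centrality <- function(profile, clusters) {
  if (!length(clusters) || is.null(names(clusters)))
    stop_allonet("clusters must be a named list", "allonet_validation_error")
  rows <- lapply(names(clusters), function(nm) {
    members <- as.character(clusters[[nm]])
    if (!length(members))
      stop_allonet(paste("empty cluster:", nm), "allonet_validation_error")
    idx <- match(members, profile$node)
    if (anyNA(idx))
      stop_allonet(paste("unknown residues in cluster", nm, ":",
                         paste(members[is.na(idx)], collapse = ", ")),
                   "allonet_validation_error")
    data.frame(cluster = nm, n = length(idx),
               mean_betweenness = mean(profile$betweenness[idx]))
  })
  do.call(rbind, rows)
}
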
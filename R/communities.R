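#' Hub residues of an interaction graph
#'
#' Nodes whose degree is at least \code{min_degree} (default 4).
#'
#' @param graph igraph
#' @param min_degree hub threshold
#' @return character vector of node names (sorted)
#' @export
find_hubs <- function(graph, min_degree = 4L) {
  deg <- igraph::degree(graph)
  nm <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  sort(nm[deg >= min_degree])
}

#' Enumerate all k-cliques of a graph
#'
#' All complete subgraphs of exactly k nodes (not only maximal ones), each
#' reported once with nodes in sorted order.
#'
#' @param graph igraph
#' @param k clique size (>= 2); the community analysis uses k = 3 and 4
#' @return object of class `clique_set`: list of sorted node-name vectors,
#'   with attribute `k`
#' @export
enumerate_k_cliques <- function(graph, k) {
  if (k < 2) stop_allonet("k must be >= 2", "allonet_parameter_error")
  cl <- igraph::cliques(graph, min = k, max = k)
  out <- lapply(cl, function(v) sort(igraph::V(graph)$name[as.integer(v)] %||%
                                       as.character(sort(as.integer(v)))))
  # deterministic order
  if (length(out)) out <- out[order(vapply(out, paste, "", collapse = "\r"))]
  structure(out, class = "clique_set", k = k,
            nodes = igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph))))
}

#' Clique-percolation communities
#'
#' Two k-cliques are adjacent when they share at least k-1 nodes (the
#' classical strict rule) or at least k-2 nodes (the relaxed rule used
#' here by default); a community is the node union of a maximal set of
#' k-cliques chained by adjacency.  Communities may overlap.
#'
#' Communities are returned sorted by decreasing size, then lexicographic
#' node order, for deterministic output.
#'
#' @param cliques a `clique_set` from [enumerate_k_cliques()]
#' @param rule "relaxed" (share >= k-2 nodes) or "strict" (share >= k-1)
#' @return object of class `community_set`: list with per-community `nodes`
#'   and member `cliques`; attributes `k`, `rule`
#' @export
clique_percolation_communities <- function(cliques, rule = c("relaxed", "strict")) {
  rule <- match.arg(rule)
  k <- attr(cliques, "k")
  m <- length(cliques)
  if (m == 0)
    return(structure(list(), class = "community_set", k = k, rule = rule))
  thr <- if (rule == "strict") k - 1L else max(1L, k - 2L)
  nodes <- unique(unlist(cliques))
  M <- matrix(0L, m, length(nodes))
  for (i in seq_len(m)) M[i, match(cliques[[i]], nodes)] <- 1L
  shared <- tcrossprod(M)
  adj <- shared >= thr
  diag(adj) <- FALSE
  cg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(cg)$membership
  comms <- lapply(seq_len(max(comp)), function(c) {
    members <- which(comp == c)
    list(nodes = sort(unique(unlist(cliques[members]))),
         cliques = cliques[members], stability = NA_real_)
  })
  ord <- order(-vapply(comms, function(x) length(x$nodes), numeric(1)),
               vapply(comms, function(x) paste(x$nodes, collapse = "\r"), ""))
  structure(comms[ord], class = "community_set", k = k, rule = rule)
}

#' @export
print.community_set <- function(x, ...) {
  cat(sprintf("community_set: %d communities (k=%s, rule=%s)\n",
              length(x), attr(x, "k"), attr(x, "rule")))
  for (cm in x)
    cat(sprintf("  [%d%s] %s\n", length(cm$nodes),
                if (is.na(cm$stability)) "" else sprintf(", stability %.3f", cm$stability),
                paste(cm$nodes, collapse = " ")))
  invisible(x)
}

community_edges <- function(community) {
  pairs <- unique(do.call(rbind, lapply(community$cliques, function(cl) {
    cb <- utils::combn(cl, 2)
    t(apply(cb, 2, sort))
  })))
  pairs
}

#' Ensemble stability filter for communities
#'
#' A community is intact in a snapshot iff every edge of every constituent
#' k-clique is present in that snapshot's graph; communities intact in more
#' than \code{threshold} of the snapshots (strict inequality) are retained,
#' with their stability fraction recorded.
#'
#' @param communities a `community_set`
#' @param egs an `ensemble_graphs` object
#' @param threshold stability threshold (default 0.75)
#' @return the filtered `community_set`, each community annotated with its
#'   stability fraction; attribute `n_dropped` records removals
#' @export
community_stability_filter <- function(communities, egs, threshold = 0.75) {
  snap_edges <- lapply(egs$graphs, function(g) {
    el <- igraph::as_edgelist(g)
    if (!nrow(el)) character(0) else
      paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  })
  kept <- list()
  n_dropped <- 0L
  for (cm in communities) {
    ed <- community_edges(cm)
    keys <- paste(ed[, 1], ed[, 2], sep = "\r")
    intact <- vapply(snap_edges, function(se) all(keys %in% se), logical(1))
    frac <- mean(intact)
    if (frac > threshold) {
      cm$stability <- frac
      kept[[length(kept) + 1L]] <- cm
    } else n_dropped <- n_dropped + 1L
  }
  structure(kept, class = "community_set", k = attr(communities, "k"),
            rule = attr(communities, "rule"), threshold = threshold,
            n_dropped = n_dropped)
}

#' Write a community set as plain text
#' @param communities a `community_set`
#' @param path output file
#' @export
write_communities <- function(communities, path) {
  k <- attr(communities, "k")
  lines <- vapply(communities, function(cm)
    sprintf("%s\t%s\t%s", k,
            ifelse(is.na(cm$stability), ".", format_value(cm$stability)),
            paste(cm$nodes, collapse = " ")), "")
  writeLines(c("k\tstability\tnodes", lines), path)
  invisible(path)
}
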
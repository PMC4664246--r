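# Independent brute-force oracles.  These deliberately share no code with the
# package implementation: exhaustive enumeration and naive double loops only.

# All-pairs shortest-path betweenness by exhaustive simple-path enumeration
# (DFS with pruning against the best length found so far).  Normalization:
# (N-1)(N-2)/2 per connected component; components < 3 nodes score 0.
brute_betweenness <- function(graph, tol = 1e-9) {
  n <- igraph::vcount(graph)
  W <- matrix(Inf, n, n)
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- if ("weight" %in% igraph::edge_attr_names(graph))
    igraph::E(graph)$weight else rep(1, nrow(el))
  for (e in seq_len(nrow(el))) {
    W[el[e, 1], el[e, 2]] <- min(W[el[e, 1], el[e, 2]], w[e])
    W[el[e, 2], el[e, 1]] <- W[el[e, 1], el[e, 2]]
  }
  comp <- igraph::components(graph)$membership
  raw <- numeric(n)
  if (n >= 2) for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (comp[s] != comp[t]) next
    paths <- list(); lens <- numeric(0); best <- Inf
    dfs <- function(v, visited, len) {
      if (len > best + 1e-6) return()
      if (v == t) {
        paths[[length(paths) + 1L]] <<- visited
        lens[length(lens) + 1L] <<- len
        if (len < best) best <<- len
        return()
      }
      for (u in which(is.finite(W[v, ]))) if (!(u %in% visited))
        dfs(u, c(visited, u), len + W[v, u])
    }
    dfs(s, s, 0)
    keep <- lens <= best + tol * max(abs(best), 1)
    sp <- paths[keep]
    for (p in sp) for (v in setdiff(p, c(s, t)))
      raw[v] <- raw[v] + 1 / length(sp)
  }
  vapply(seq_len(n), function(i) {
    N <- sum(comp == comp[i])
    if (N >= 3) raw[i] / ((N - 1) * (N - 2) / 2) else 0
  }, numeric(1))
}

# Naive O(n^2) side-chain contact count between two residues.
brute_contacts <- function(structure, ri, rj, cutoff = 4.5) {
  a <- structure$atoms
  rt <- residue_table(structure)
  if (rt$chain[ri] == rt$chain[rj] && abs(rt$resno[ri] - rt$resno[rj]) == 1)
    return(0L)
  sidechain_of <- function(r) {
    idx <- which(a$res_index == r & a$is_heavy &
                   !(a$elety %in% c("N", "CA", "C", "O", "OXT")))
    if (!length(idx)) idx <- which(a$res_index == r & a$elety == "CA")
    idx
  }
  ai <- sidechain_of(ri); aj <- sidechain_of(rj)
  count <- 0L
  for (p in ai) for (q in aj)
    if (sqrt(sum((structure$xyz[p, ] - structure$xyz[q, ])^2)) <= cutoff)
      count <- count + 1L
  count
}

# Exhaustive exposed-point atom depth: every sample point of every atom is
# tested against every other atom's accessible sphere by plain loops.
brute_atom_depths <- function(xyz, radii, probe = 1.4, npts = 128L) {
  n <- nrow(xyz)
  acc <- radii + probe
  i0 <- seq_len(npts) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(npts) - 1)
  z <- 1 - 2 * i0 / npts
  rr <- sqrt(pmax(0, 1 - z^2))
  unit <- cbind(rr * cos(phi), rr * sin(phi), z)
  cloud <- NULL
  for (i in seq_len(n)) {
    for (k in seq_len(npts)) {
      p <- xyz[i, ] + acc[i] * unit[k, ]
      outside <- TRUE
      for (j in seq_len(n)) {
        if (j == i) next
        if (sum((p - xyz[j, ])^2) < acc[j]^2) { outside <- FALSE; break }
      }
      if (outside) cloud <- rbind(cloud, p)
    }
  }
  depth <- numeric(n)
  for (i in seq_len(n)) {
    dmin <- Inf
    for (k in seq_len(nrow(cloud)))
      dmin <- min(dmin, sqrt(sum((cloud[k, ] - xyz[i, ])^2)))
    depth[i] <- max(0, dmin - acc[i])
  }
  depth
}

# Naive pairwise interaction energy (LJ 12-6 + screened Coulomb) between two
# atom index sets of a structure; same physics as the default backend but
# written as explicit loops.
brute_interaction_energy <- function(structure, set1, set2,
                                     params = allonet:::DEFAULT_PAIR_PARAMS,
                                     coulomb_k = 332.06) {
  a <- structure$atoms
  q <- if (!is.null(a$charge)) a$charge else rep(0, nrow(a))
  e_vdw <- 0; e_elec <- 0
  for (i in set1) for (j in set2) {
    if (!a$is_heavy[i] || !a$is_heavy[j]) next
    r <- sqrt(sum((structure$xyz[i, ] - structure$xyz[j, ])^2))
    si <- params$sigma[match(a$element[i], params$element)]
    sj <- params$sigma[match(a$element[j], params$element)]
    ei <- params$epsilon[match(a$element[i], params$element)]
    ej <- params$epsilon[match(a$element[j], params$element)]
    sij <- (si + sj) / 2; eij <- sqrt(ei * ej)
    e_vdw <- e_vdw + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    e_elec <- e_elec + coulomb_k * q[i] * q[j] / (4 * r * r)
  }
  list(E_vdw = e_vdw, E_elec = e_elec)
}

# Classical clique percolation (strict k-1 rule) by naive pairwise chaining.
naive_cpm <- function(cliques, k) {
  m <- length(cliques)
  if (!m) return(list())
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i < j && length(intersect(cliques[[i]], cliques[[j]])) >= k - 1) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  lapply(unique(roots), function(r)
    sort(unique(unlist(cliques[roots == r]))))
}

# Random test graph with vertex names.
random_graph <- function(n, p, weighted = FALSE, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n) < p, n, n)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A | t(A), mode = "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(n))
  if (weighted) igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.1, 2)
  g
}

# Quick labelled graph from an edge list written as "a-b" strings.
graph_from_pairs <- function(pairs, nodes = NULL) {
  el <- do.call(rbind, strsplit(pairs, "-", fixed = TRUE))
  nodes <- nodes %||% sort(unique(as.vector(el)))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  igraph::add_edges(g, match(t(el), nodes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 5 single-atom residues on the x-axis; the last residue oscillates by
# +-delta, so its mean distance to its partners (residues 1-3; residue 4 is
# the excluded sequence neighbour) alternates by exactly 2*delta, giving
# Var(d) = delta^2 exactly.
line_oscillator <- function(delta, n_frames = 4) {
  atoms <- allonet:::make_atom_table(rep("CA", 5), rep("C", 5), "A", 1:5, "", "GLY")
  base <- cbind(c(0, 4, 8, 12, 30), 0, 0)
  frames <- t(vapply(seq_len(n_frames), function(f) {
    co <- base; co[5, 1] <- co[5, 1] + delta * (-1)^f
    allonet:::flat_xyz(co)
  }, numeric(15)))
  new_ensemble(atoms, frames)
}
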
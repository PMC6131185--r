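# Independent brute-force oracles used against the package's algorithms.

# connected components by boolean-matrix transitive closure
closureComponents <- function(n, edges) {
  A <- diag(TRUE, n)
  if (nrow(edges)) {
    A[edges] <- TRUE
    A[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  memb <- apply(A, 1, function(r) min(which(r)))
  comps <- lapply(split(seq_len(n), memb), sort)
  comps[order(vapply(comps, min, 1L))]
}

# maximum number of vertex-disjoint source-target paths (Menger) via
# max-flow with vertex splitting and unit vertex capacities
mengerNumber <- function(g, sources, targets) {
  n <- igraph::vcount(g)
  vn <- igraph::V(g)$name
  if (is.null(vn)) vn <- as.character(seq_len(n))
  din <- paste0(vn, ".in"); dout <- paste0(vn, ".out")
  h <- igraph::make_empty_graph(directed = TRUE)
  h <- igraph::add_vertices(h, 2 * n + 2, name = c(din, dout, "SRC", "SNK"))
  eds <- character(0); caps <- numeric(0)
  add <- function(a, b, cp) { eds <<- c(eds, a, b); caps <<- c(caps, cp) }
  for (q in seq_len(n)) add(din[q], dout[q], 1)
  if (igraph::ecount(g)) {
    ends <- igraph::ends(g, igraph::E(g))
    for (q in seq_len(nrow(ends))) {
      a <- match(ends[q, 1], vn); b <- match(ends[q, 2], vn)
      add(dout[a], din[b], Inf); add(dout[b], din[a], Inf)
    }
  }
  for (s in sources) add("SRC", paste0(s, ".in"), 1)
  for (t in targets) add(paste0(t, ".out"), "SNK", 1)
  h <- igraph::add_edges(h, eds)
  igraph::max_flow(h, "SRC", "SNK", capacity = caps)$value
}

# seeded random undirected graph with named vertices 1..n
randomNamedGraph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, n, name = as.character(seq_len(n)))
  if (any(keep))
    g <- igraph::add_edges(g, as.vector(t(matrix(as.character(pairs[keep, ]),
                                                 ncol = 2))))
  g
}

# minimum vertex-cost (sum of phi over path vertices) over all simple
# source->target paths, by exhaustive enumeration
exhaustiveMinVertexCost <- function(g, phi, sources, targets) {
  vn <- igraph::V(g)$name
  best <- Inf
  for (s in intersect(sources, vn)) {
    sp <- igraph::all_simple_paths(g, from = s,
                                   to = intersect(targets, vn))
    for (p in sp) {
      cost <- sum(phi[igraph::as_ids(p)])
      if (cost < best) best <- cost
    }
  }
  best
}

# small all-water toy tessellation for path-search oracles: nWater waters
# scattered in a box above/below a thin protein sheet is not needed --
# random waters plus a couple of protein sites for the potential
makeToyWaterTess <- function(nWater, seed, box = 12) {
  set.seed(seed)
  repeat {
    wat <- matrix(runif(nWater * 3, 1.5, box - 1.5), ncol = 3)
    if (nWater < 2 || min(dist(wat)) > 1.6) break
  }
  prot <- rbind(c(box / 2, box / 2, box / 2), c(2, 2, 2))
  sites <- rbind(
    weightedSites(wat, weight = 1.48, kind = "water", chain = "W",
                  resname = "HOH", atom = "O"),
    weightedSites(prot, weight = 0, kind = "protein", chain = "P",
                  resname = "GLY", atom = "CA"))
  sites$id <- seq_len(nrow(sites))
  sites$resno <- seq_len(nrow(sites))
  buildTessellation(sites, boxRegion(c(0, 0, 0), rep(box, 3)))
}
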
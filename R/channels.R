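#' Source/target regions for traversing-path searches
#'
#' Delimits the search sub-domain: the minimal enclosing sphere of the
#' protein augmented by the standard water radius (1.4 Angstrom), a source
#' shell of waters in a thin slab just above the membrane on the
#' extracellular side, and target waters below the membrane (periplasm).
#' These are operational definitions; the shell thickness and augmentation
#' are configurable.
#'
#' @param tess A [LaguerreTessellation-class].
#' @param cfg A [GroupingConfig-class] (membrane axis and slab).
#' @param shellThickness Thickness (Angstrom) of the extracellular source
#'   shell above the membrane slab.
#' @param augment Radius added to the protein enclosing sphere (Angstrom).
#' @param sourceIds Optional explicit water source ids (e.g. from
#'   [envelopeWaterSources()]), overriding the shell rule.
#' @return List with `centre`, `radius` (augmented), `axis` (1-3), `slab`,
#'   `waterIds` (waters inside the sphere), `sourceIds`, `targetIds`.
#' @export
pathRegions <- function(tess, cfg, shellThickness = 3, augment = 1.4,
                        sourceIds = NULL) {
  s <- tess@sites
  ax <- match(cfg@membraneAxis, c("x", "y", "z"))
  slab <- membraneSlab(s, cfg)
  prot <- s$kind == "protein"
  if (!any(prot)) stop("no protein sites")
  pp <- as.matrix(s[prot, c("x", "y", "z")])
  sph <- enclosingSphere(pp)
  R <- sph$radius + augment
  wat <- setdiff(siteSelect(tess, kind = "water"), tess@emptyCells)
  wp <- as.matrix(s[match(wat, s$id), c("x", "y", "z")])
  inSphere <- sqrt(colSums((t(wp) - sph$centre)^2)) <= R
  waterIds <- wat[inSphere]
  zc <- s[match(waterIds, s$id), c("x", "y", "z")[ax]]
  if (is.null(sourceIds))
    sourceIds <- waterIds[zc > slab[2] & zc <= slab[2] + shellThickness]
  else sourceIds <- intersect(sourceIds, waterIds)
  targetIds <- waterIds[zc < slab[1]]
  list(centre = sph$centre, radius = R, axis = ax, slab = slab,
       waterIds = waterIds, sourceIds = sourceIds, targetIds = targetIds)
}

# Ritter's two-pass approximation of the minimal enclosing sphere.
enclosingSphere <- function(pts) {
  p0 <- pts[1, ]
  i <- which.max(colSums((t(pts) - p0)^2))
  j <- which.max(colSums((t(pts) - pts[i, ])^2))
  ctr <- (pts[i, ] + pts[j, ]) / 2
  r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
  for (q in seq_len(nrow(pts))) {
    d <- sqrt(sum((pts[q, ] - ctr)^2))
    if (d > r) {
      r <- (r + d) / 2
      ctr <- ctr + (d - r) / d * (pts[q, ] - ctr)
    }
  }
  list(centre = ctr, radius = r)
}

#' Cost model for widest-path searches
#'
#' The per-vertex potential is
#' `phi(x) = (refDist / d(x, prot))^exponent + m(x) * (refDist / dp)^exponent`,
#' where `d(x, prot)` is the distance to the closest protein atom and `m(x)`
#' counts how many previously found paths visited `x`.  `dp = 0.1` makes the
#' overlap penalty huge (strictly disjoint paths); `dp = 1` tolerates small
#' overlaps (soft bundles).
#'
#' @param dp Overlap penalty scale (Angstrom); must be positive.
#' @param refDist Reference distance in the numerator (Angstrom).
#' @param exponent Potential exponent.
#' @param maxCost Iteration stops once the cheapest remaining path costs at
#'   least this much.
#' @return List with the model parameters.
#' @export
costModel <- function(dp = 0.1, refDist = 3, exponent = 6, maxCost = 1e6) {
  stopifnot(dp > 0, refDist > 0, exponent > 0)
  list(dp = dp, refDist = refDist, exponent = exponent, maxCost = maxCost)
}

#' @rdname costModel
#' @param d Distance(s) to the nearest protein atom (Angstrom).
#' @param m Visit multiplicit(y/ies) from previous path iterations.
#' @param cost A cost model list.
#' @return `costPotential`: the potential value(s).
#' @export
costPotential <- function(d, m = 0, cost = costModel()) {
  (cost$refDist / d)^cost$exponent + m * (cost$refDist / cost$dp)^cost$exponent
}

# igraph over given water ids with Euclidean edge lengths
waterGraph <- function(tess, ids) {
  g <- contactGraph(tess, ids)
  if (igraph::ecount(g) > 0) {
    s <- tess@sites
    ends <- igraph::ends(g, igraph::E(g))
    p1 <- as.matrix(s[match(as.integer(ends[, 1]), s$id), c("x", "y", "z")])
    p2 <- as.matrix(s[match(as.integer(ends[, 2]), s$id), c("x", "y", "z")])
    igraph::E(g)$weight <- sqrt(rowSums((p1 - p2)^2))
  }
  g
}

newWaterPath <- function(nodes, costTotal) {
  new("WaterPath", nodes = as.integer(nodes), totalCost = costTotal,
      classification = NA_character_, profile = data.frame())
}

#' @describeIn WaterPath-class Compact display.
#' @param object A `WaterPath`.
#' @export
setMethod("show", "WaterPath", function(object) {
  cat(sprintf("WaterPath: %d nodes, total cost %.4g%s\n",
              length(object@nodes), object@totalCost,
              if (is.na(object@classification)) ""
              else paste0(", ", object@classification)))
  invisible(object)
})

#' @rdname WaterPath-class
#' @param path A `WaterPath`.
#' @export
pathNodes <- function(path) path@nodes

#' Node-disjoint shortest traversing water paths
#'
#' Iterated Dijkstra with exclusion: find the minimum-Euclidean-length
#' source-to-target path in the water contact graph, remove its nodes, and
#' repeat until no traversing path remains.  The number of paths found (DP)
#' probes channel multiplicity and constriction; the greedy shortest-first
#' removal is a lower bound on the Menger (maximum vertex-disjoint) number.
#'
#' @param tess A [LaguerreTessellation-class].
#' @param regions Regions from [pathRegions()].
#' @return List with `paths` (list of [WaterPath-class], discovery order)
#'   and `census` (one-row data.frame `DP`, `e_chan`, `p_chan` from
#'   [openingCensus()]).
#' @export
shortestDisjointPaths <- function(tess, regions) {
  g <- waterGraph(tess, regions$waterIds)
  found <- greedyDisjointPaths(g, as.character(regions$sourceIds),
                               as.character(regions$targetIds))
  paths <- lapply(found, function(p) newWaterPath(as.integer(p$nodes), p$length))
  for (q in seq_along(paths))
    paths[[q]]@classification <- classifyPath(paths[[q]], regions, tess)
  list(paths = paths, census = openingCensus(paths, regions, tess))
}

# Greedy shortest-first node-disjoint extraction on an igraph with vertex
# names: repeatedly take the minimum-weight source->target path and delete
# its vertices.  Returns list(nodes = name vector, length = path weight).
# A lower bound on the Menger number (can undercount on adversarial graphs).
greedyDisjointPaths <- function(g, sources, targets) {
  out <- list()
  repeat {
    vn <- igraph::V(g)$name
    src <- intersect(sources, vn)
    tgt <- intersect(targets, vn)
    if (!length(src) || !length(tgt)) break
    D <- igraph::distances(g, v = src, to = tgt)
    if (!any(is.finite(D))) break
    best <- which(D == min(D), arr.ind = TRUE)[1, ]
    sp <- igraph::shortest_paths(g, from = src[best[1]], to = tgt[best[2]],
                                 output = "vpath")
    nodes <- igraph::as_ids(sp$vpath[[1]])
    out[[length(out) + 1L]] <- list(nodes = nodes, length = min(D))
    g <- igraph::delete_vertices(g, nodes)
  }
  out
}

#' Widest traversing water paths
#'
#' Iterated Dijkstra on the water contact graph with the vertex potential of
#' [costModel()] (cost is accrued on vertices, endpoints included; edge
#' length does not enter).  After each found path the visit multiplicity
#' `m(x)` of its nodes is incremented, penalising overlap in later
#' iterations.  Paths are returned in discovery order with non-decreasing
#' cost; iteration stops after `nIter` paths or when the cheapest remaining
#' path reaches `cost$maxCost`.
#'
#' @inheritParams shortestDisjointPaths
#' @param cost A [costModel()].
#' @param nIter Maximum number of paths to extract.
#' @param includeLigand Count ligand atoms as protein for the
#'   distance-to-protein potential (they physically constrict channels).
#' @return List of [WaterPath-class] with classification and radius profile
#'   filled in.
#' @export
widestPaths <- function(tess, regions, cost = costModel(), nIter = 3,
                        includeLigand = TRUE) {
  s <- tess@sites
  protKinds <- if (includeLigand) c("protein", "ligand") else "protein"
  protPos <- as.matrix(s[s$kind %in% protKinds, c("x", "y", "z")])
  ids <- regions$waterIds
  wp <- as.matrix(s[match(ids, s$id), c("x", "y", "z")])
  dProt <- nn_dist_cpp(wp, protPos)
  phi0 <- (cost$refDist / dProt)^cost$exponent
  penalty <- (cost$refDist / cost$dp)^cost$exponent
  m <- integer(length(ids))
  g0 <- contactGraph(tess, ids)
  src <- intersect(as.character(regions$sourceIds), igraph::V(g0)$name)
  tgt <- intersect(as.character(regions$targetIds), igraph::V(g0)$name)
  if (!length(src) || !length(tgt)) return(list())
  # super source/sink carrying the endpoint half-costs
  gS <- igraph::add_vertices(g0, 2, name = c(".S", ".T"))
  gS <- igraph::add_edges(gS, as.vector(rbind(".S", src)))
  gS <- igraph::add_edges(gS, as.vector(rbind(tgt, ".T")))
  ends <- igraph::ends(gS, igraph::E(gS))
  paths <- list()
  for (iter in seq_len(nIter)) {
    phi <- phi0 + m * penalty
    vphi <- setNames(c(phi, 0, 0), c(as.character(ids), ".S", ".T"))
    w <- (vphi[ends[, 1]] + vphi[ends[, 2]]) / 2
    D <- igraph::distances(gS, v = ".S", to = ".T", weights = w)
    if (!is.finite(D[1, 1]) || D[1, 1] >= cost$maxCost) break
    sp <- igraph::shortest_paths(gS, from = ".S", to = ".T", weights = w,
                                 output = "vpath")
    vn <- igraph::as_ids(sp$vpath[[1]])
    nodes <- as.integer(vn[!vn %in% c(".S", ".T")])
    pth <- newWaterPath(nodes, as.numeric(D[1, 1]))
    pth@classification <- classifyPath(pth, regions, tess)
    pth@profile <- radiusProfile(tess, pth, includeLigand = includeLigand)
    paths[[length(paths) + 1L]] <- pth
    m[match(nodes, ids)] <- m[match(nodes, ids)] + 1L
  }
  paths
}

#' Classify a traversing path as direct or indirect
#'
#' The protein envelope is the membrane slab intersected with the augmented
#' enclosing sphere.  A path is direct when, once it has entered the
#' envelope, it stays inside until its final exit; a path that escapes to
#' the external domain between entry and exit (where the cost is low) and
#' re-enters through another opening is indirect.
#'
#' @param path A [WaterPath-class].
#' @param regions Regions from [pathRegions()].
#' @param tess The tessellation the path lives in.
#' @return `"direct"` or `"indirect"`.
#' @export
classifyPath <- function(path, regions, tess) {
  s <- tess@sites
  p <- as.matrix(s[match(path@nodes, s$id), c("x", "y", "z")])
  zc <- p[, regions$axis]
  inSphere <- sqrt(colSums((t(p) - regions$centre)^2)) <= regions$radius
  inEnv <- inSphere & zc >= regions$slab[1] & zc <= regions$slab[2]
  if (!any(inEnv)) return("indirect")
  rng <- range(which(inEnv))
  if (all(inEnv[rng[1]:rng[2]])) "direct" else "indirect"
}

#' Radius profile of a path
#'
#' Per node: `z`, the coordinate along the membrane axis with origin at the
#' protein centroid, and `r`, the Euclidean distance to the nearest protein
#' atom centre.  The effective channel radius subtracts a van der Waals
#' radius (default 1.1 Angstrom), floored at 0.
#'
#' @param tess A [LaguerreTessellation-class].
#' @param path A [WaterPath-class].
#' @param axis Membrane axis index (1-3), default 3 (z).
#' @param vdw Van der Waals radius subtracted for the effective radius.
#' @param includeLigand Count ligand atoms as protein for distances.
#' @return data.frame with `z`, `r`, `reff` per path node.
#' @export
radiusProfile <- function(tess, path, axis = 3, vdw = 1.1,
                          includeLigand = TRUE) {
  s <- tess@sites
  protKinds <- if (includeLigand) c("protein", "ligand") else "protein"
  prot <- as.matrix(s[s$kind %in% protKinds, c("x", "y", "z")])
  if (!nrow(prot)) stop("no protein sites")
  p <- as.matrix(s[match(path@nodes, s$id), c("x", "y", "z")])
  r <- nn_dist_cpp(p, prot)
  data.frame(z = p[, axis] - mean(prot[, axis]), r = r,
             reff = pmax(r - vdw, 0))
}

#' Count distinct openings used by a set of paths
#'
#' Entry points are each path's first node inside the protein envelope,
#' exit points the last; each set is single-linkage clustered at cutoff
#' `dOpen` and the cluster counts give the number of extracellular
#' (`e_chan`) and periplasmic (`p_chan`) openings.
#'
#' @param paths List of [WaterPath-class].
#' @param regions Regions from [pathRegions()].
#' @param tess The tessellation.
#' @param dOpen Single-linkage cutoff (Angstrom).
#' @return One-row data.frame `DP`, `e_chan`, `p_chan`.
#' @export
openingCensus <- function(paths, regions, tess, dOpen = 6) {
  if (!length(paths))
    return(data.frame(DP = 0L, e_chan = 0L, p_chan = 0L))
  s <- tess@sites
  pickEnd <- function(path, first) {
    p <- as.matrix(s[match(path@nodes, s$id), c("x", "y", "z")])
    zc <- p[, regions$axis]
    inSphere <- sqrt(colSums((t(p) - regions$centre)^2)) <= regions$radius
    inEnv <- inSphere & zc >= regions$slab[1] & zc <= regions$slab[2]
    idx <- if (any(inEnv)) { if (first) min(which(inEnv)) else max(which(inEnv)) }
           else { if (first) 1L else length(path@nodes) }
    p[idx, ]
  }
  nClust <- function(P) {
    if (nrow(P) <= 1) return(nrow(P))
    max(cutree(hclust(dist(P), method = "single"), h = dOpen))
  }
  entries <- do.call(rbind, lapply(paths, pickEnd, first = TRUE))
  exits <- do.call(rbind, lapply(paths, pickEnd, first = FALSE))
  data.frame(DP = length(paths), e_chan = nClust(entries), p_chan = nClust(exits))
}

#' Ligand contact envelope across snapshots
#'
#' The set of residues that share a Laguerre face with any ligand atom in
#' every supplied snapshot.  It defines the ligand binding site even in
#' snapshots where the ligand is absent.
#'
#' @param tessList List of ligand-containing [LaguerreTessellation-class].
#' @return Character vector of residue tags `"chain:resno:resname"`.
#' @export
ligandContactEnvelope <- function(tessList) {
  if (!length(tessList)) stop("no snapshots given")
  perSnap <- lapply(tessList, function(tess) {
    lig <- siteSelect(tess, kind = "ligand")
    if (!length(lig)) stop("snapshot without ligand atoms")
    a <- tess@adjacency
    other <- unique(c(a[a[, 2] %in% lig, 1], a[a[, 1] %in% lig, 2]))
    residueTags(tess@sites, intersect(other, siteSelect(tess, kind = "protein")))
  })
  Reduce(intersect, perSnap)
}

#' @rdname ligandContactEnvelope
#' @param tess A tessellation (with or without ligand).
#' @param envelope Residue tags from `ligandContactEnvelope`.
#' @return `envelopeWaterSources`: integer ids of waters in contact with any
#'   envelope residue, usable as `sourceIds` in [pathRegions()].
#' @export
envelopeWaterSources <- function(tess, envelope) {
  s <- tess@sites
  tags <- paste(s$chain, s$resno, s$resname, sep = ":")
  envSites <- s$id[tags %in% envelope & s$kind == "protein"]
  a <- tess@adjacency
  other <- unique(c(a[a[, 2] %in% envSites, 1], a[a[, 1] %in% envSites, 2]))
  intersect(other, siteSelect(tess, kind = "water"))
}

#' Write paths as CSV (one row per node)
#'
#' @param paths List of [WaterPath-class].
#' @param tess The tessellation.
#' @param path Output path.
#' @return Invisibly, the data.frame written.
#' @export
writePathReport <- function(paths, tess, path) {
  s <- tess@sites
  rows <- lapply(seq_along(paths), function(q) {
    p <- paths[[q]]
    pos <- s[match(p@nodes, s$id), c("x", "y", "z")]
    prof <- if (nrow(p@profile)) p@profile else
      data.frame(z = NA_real_, r = NA_real_, reff = NA_real_)[rep(1, length(p@nodes)), ]
    data.frame(path = q, rank = seq_along(p@nodes), node = p@nodes,
               x = pos$x, y = pos$y, z = pos$z,
               r = prof$r, z_profile = prof$z,
               classification = p@classification,
               total_cost = p@totalCost)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
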
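#' Assemble a weighted-site table
#'
#' Builds the canonical site data.frame consumed by [buildTessellation()].
#' Water oxygen sites normally carry the calibrated water weight (1.48
#' Angstrom^2 by default elsewhere); all other atoms carry weight 0.
#'
#' @param pos n x 3 coordinate matrix (Angstrom).
#' @param weight Site weights (Angstrom^2), recycled; weight is the squared
#'   effective radius of the site.
#' @param kind Group tag per site: one of `"protein"`, `"water"`, `"lipid"`,
#'   `"ion"`, `"ligand"` (recycled).
#' @param chain,resno,resname,atom Residue bookkeeping (recycled).
#' @return data.frame with columns `id, x, y, z, weight, kind, chain, resno,
#'   resname, atom`.
#' @export
weightedSites <- function(pos, weight = 0, kind = "protein", chain = "A",
                          resno = NA_integer_, resname = "UNK", atom = "X") {
  pos <- matrix(as.numeric(as.matrix(pos)), ncol = 3)
  n <- nrow(pos)
  if (!all(is.finite(pos))) stop("site positions must be finite")
  w <- rep_len(as.numeric(weight), n)
  if (any(w < 0)) stop("weights must be non-negative")
  rn <- rep_len(as.integer(resno), n)
  if (all(is.na(rn))) rn <- seq_len(n)
  data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3],
             weight = w, kind = rep_len(kind, n), chain = rep_len(chain, n),
             resno = rn, resname = rep_len(resname, n),
             atom = rep_len(atom, n), stringsAsFactors = FALSE)
}

#' Radical plane between two weighted sites
#'
#' The plane of points with equal power distance to both sites,
#' `|x - p1|^2 - w1 = |x - p2|^2 - w2`; it carries the Laguerre face
#' separating their cells.
#'
#' @param p1,p2 Length-3 positions.
#' @param w1,w2 Weights (Angstrom^2).
#' @return List with unit `normal` (pointing from site 1 to site 2), scalar
#'   `offset` such that the plane is `normal . x = offset`, and `t`, the
#'   signed distance of the plane from `p1` along `normal`.
#' @examples
#' # equal weights: bisector halfway between the sites
#' radicalPlane(c(0, 0, 0), 0, c(2, 0, 0), 0)$t  # 1
#' @export
radicalPlane <- function(p1, w1, p2, w2) {
  d <- as.numeric(p2) - as.numeric(p1)
  dd <- sqrt(sum(d^2))
  if (dd == 0) stop("radical plane undefined for coincident sites")
  n <- d / dd
  t <- (dd^2 + w1 - w2) / (2 * dd)
  list(normal = n, offset = sum(n * as.numeric(p1)) + t, t = t)
}

#' Build the Laguerre (power) tessellation of a weighted site set
#'
#' Partitions the bounded region into convex Laguerre polyhedra, one per
#' site (possibly empty for sites swallowed by heavier neighbours).  Each
#' cell is obtained by clipping the region by the radical planes against all
#' sites that can cut it, scanned in order of increasing distance with a
#' security-radius stop.  The polygonal faces between cells, the cell
#' volumes and the dual contact (regular-triangulation) graph all come from
#' this single construction, so the face/adjacency/dual-edge duality holds
#' by construction.
#'
#' @param sites Site data.frame from [weightedSites()] / [prepareSites()],
#'   or an n x 3 coordinate matrix (then `weight` applies).
#' @param region A [BoundedRegion-class]; default: a box fitted around the
#'   sites with 5 Angstrom padding.
#' @param weight Weights used when `sites` is a bare matrix.
#' @param epsScale Relative geometric tolerance (times the region diagonal)
#'   used to classify vertices against cutting planes.
#' @param sliverTol Faces with area below this (Angstrom^2) are numerical
#'   slivers: dropped from the face list and the adjacency.
#' @param boundary `"clip"` (default) truncates cells by the region walls;
#'   `"mirror"` materialises the box walls by ghost sites reflected through
#'   each face (exact for boxes, since the radical plane to an equal-weight
#'   mirror image is the wall itself).  Both give identical geometry for box
#'   regions; mirroring is not available for spheres.
#' @return A [LaguerreTessellation-class].
#' @examples
#' s <- weightedSites(rbind(c(0, 0, 0), c(2, 0, 0)))
#' tess <- buildTessellation(s, boxRegion(c(-4, -4, -4), c(6, 4, 4)))
#' cellVolumes(tess)
#' @export
buildTessellation <- function(sites, region = NULL, weight = 0,
                              epsScale = 1e-10, sliverTol = 1e-10,
                              boundary = c("clip", "mirror")) {
  boundary <- match.arg(boundary)
  if (!is.data.frame(sites)) sites <- weightedSites(sites, weight = weight)
  if (nrow(sites) < 2) stop("at least 2 sites are required")
  pos <- as.matrix(sites[, c("x", "y", "z")])
  if (!all(is.finite(pos))) stop("site positions must be finite")
  key <- paste(round(pos[, 1], 9), round(pos[, 2], 9), round(pos[, 3], 9),
               round(sites$weight, 12))
  if (anyDuplicated(key))
    stop("coincident sites with identical position and weight; deduplicate first")
  if (is.null(region)) region <- boxRegion(sites = pos, padding = 5)
  if (!all(regionContains(region, pos)))
    stop("all sites must lie strictly inside the region")
  bb <- regionBox(region)
  if (boundary == "mirror") {
    if (region@shape != "box") stop("ghost mirroring is only defined for box regions")
    n <- nrow(pos)
    ghostPos <- NULL; ghostWall <- integer(0)
    for (ax in 1:3) for (side in 1:2) {
      gp <- pos
      wallCoord <- if (side == 1) bb$lo[ax] else bb$hi[ax]
      gp[, ax] <- 2 * wallCoord - gp[, ax]
      ghostPos <- rbind(ghostPos, gp)
      ghostWall <- c(ghostWall, rep.int(-(2 * (ax - 1) + side), n))
    }
    ext <- max(bb$hi - bb$lo)
    res <- laguerre_cpp(rbind(pos, ghostPos), rep(sites$weight, 7),
                        bb$lo - ext, bb$hi + ext,
                        matrix(numeric(0), 0, 4), epsScale, sliverTol)
    keepF <- res$face_i <= n
    fj <- res$face_j[keepF]
    fj[fj > n] <- ghostWall[fj[fj > n] - n]        # ghost contact = wall face
    res <- list(volumes = res$volumes[seq_len(n)],
                empty = res$empty[seq_len(n)],
                boundary = res$boundary[seq_len(n)] | vapply(
                  split(fj < 0, res$face_i[keepF])[as.character(seq_len(n))],
                  function(x) isTRUE(any(x)), TRUE),
                face_i = res$face_i[keepF], face_j = fj,
                face_area = res$face_area[keepF],
                face_poly = res$face_poly[keepF])
  } else {
    res <- laguerre_cpp(pos, sites$weight, bb$lo, bb$hi, regionPlanes(region),
                        epsScale, sliverTol)
  }
  faces <- data.frame(i = res$face_i, j = res$face_j, area = res$face_area)
  real <- faces$j > 0
  adj <- cbind(i = faces$i[real], j = faces$j[real])
  tess <- new("LaguerreTessellation", sites = sites, region = region,
              volumes = as.numeric(res$volumes), faces = faces,
              facePolys = res$face_poly, adjacency = adj,
              emptyCells = which(res$empty), boundaryCells = which(res$boundary))
  if (length(tess@emptyCells))
    message(length(tess@emptyCells), " empty Laguerre cell(s) detected (ids: ",
            paste(head(tess@emptyCells, 5), collapse = ", "),
            if (length(tess@emptyCells) > 5) ", ..." else "", ")")
  tess
}

#' @rdname LaguerreTessellation-class
#' @param object,tess A `LaguerreTessellation`.
#' @export
setMethod("show", "LaguerreTessellation", function(object) {
  cat(sprintf("LaguerreTessellation: %d sites, %d faces, %d contacts\n",
              nrow(object@sites), nrow(object@faces), nrow(object@adjacency)))
  cat(sprintf("  kinds: %s\n",
              paste(sprintf("%s=%d", names(table(object@sites$kind)),
                            table(object@sites$kind)), collapse = " ")))
  cat(sprintf("  total cell volume %.4f A^3 (region %.4f A^3); %d empty, %d boundary cells\n",
              sum(object@volumes), regionVolume(object@region),
              length(object@emptyCells), length(object@boundaryCells)))
  invisible(object)
})

#' @rdname LaguerreTessellation-class
#' @export
cellVolumes <- function(tess) setNames(tess@volumes, tess@sites$id)

#' @rdname LaguerreTessellation-class
#' @export
siteTable <- function(tess) tess@sites

#' @rdname LaguerreTessellation-class
#' @export
faceTable <- function(tess) tess@faces

#' @rdname LaguerreTessellation-class
#' @export
adjacencyPairs <- function(tess) tess@adjacency

#' @rdname LaguerreTessellation-class
#' @export
emptyCells <- function(tess) tess@emptyCells

#' @rdname LaguerreTessellation-class
#' @export
boundaryCells <- function(tess) tess@boundaryCells

#' @rdname LaguerreTessellation-class
#' @export
tessRegion <- function(tess) tess@region

#' Select site ids by group, chain or residue
#'
#' @param tess A [LaguerreTessellation-class] (or a site data.frame).
#' @param kind,chain,resname Optional filters (character vectors).
#' @param resno Optional residue numbers (vector) or a length-2 range given
#'   as `range = c(lo, hi)`.
#' @param range Optional inclusive residue-number range.
#' @return Integer site ids.
#' @export
siteSelect <- function(tess, kind = NULL, chain = NULL, resno = NULL,
                       resname = NULL, range = NULL) {
  s <- if (is.data.frame(tess)) tess else tess@sites
  keep <- rep(TRUE, nrow(s))
  if (!is.null(kind)) keep <- keep & s$kind %in% kind
  if (!is.null(chain)) keep <- keep & s$chain %in% chain
  if (!is.null(resno)) keep <- keep & s$resno %in% resno
  if (!is.null(resname)) keep <- keep & s$resname %in% resname
  if (!is.null(range)) keep <- keep & s$resno >= range[1] & s$resno <= range[2]
  s$id[keep]
}

#' Interface area between two site groups
#'
#' Sum of the areas of Laguerre faces whose two sites fall one in each
#' group.  Symmetric and additive over disjoint groups.
#'
#' @param tess A [LaguerreTessellation-class].
#' @param groupA,groupB Disjoint integer site-id sets.
#' @return Area in Angstrom^2 (0 when the groups share no face).
#' @export
interfaceArea <- function(tess, groupA, groupB) {
  groupA <- as.integer(groupA); groupB <- as.integer(groupB)
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  f <- tess@faces
  real <- f$j > 0
  hit <- real & ((f$i %in% groupA & f$j %in% groupB) |
                 (f$i %in% groupB & f$j %in% groupA))
  sum(f$area[hit])
}

#' Contact graph of (a subset of) the tessellation
#'
#' Vertices are site ids, edges the Laguerre face contacts (equivalently the
#' regular-triangulation edges) with both ends in the subset.
#'
#' @param tess A [LaguerreTessellation-class].
#' @param subset Integer site ids (default: all sites with non-empty cells).
#' @return An [igraph::graph] whose vertex `name` attribute holds site ids.
#' @export
contactGraph <- function(tess, subset = NULL) {
  if (is.null(subset))
    subset <- setdiff(tess@sites$id, tess@emptyCells)
  subset <- as.integer(subset)
  a <- tess@adjacency
  keep <- a[, 1] %in% subset & a[, 2] %in% subset
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(subset), name = as.character(subset))
  if (any(keep)) {
    ep <- rbind(as.character(a[keep, 1]), as.character(a[keep, 2]))
    g <- igraph::add_edges(g, as.vector(ep))
  }
  g
}

# Per-cell clipping planes reconstructed analytically (radical planes of the
# realised contacts + region walls).  Used by the Monte-Carlo membership check.
cellPlaneSet <- function(tess) {
  s <- tess@sites
  pos <- as.matrix(s[, c("x", "y", "z")])
  n <- nrow(s)
  a <- tess@adjacency
  planes <- vector("list", n)
  addPlane <- function(i, row) planes[[i]][[length(planes[[i]]) + 1L]] <<- row
  for (i in seq_len(n)) planes[[i]] <- list()
  for (k in seq_len(nrow(a))) {
    i <- a[k, 1]; j <- a[k, 2]
    rp <- radicalPlane(pos[i, ], s$weight[i], pos[j, ], s$weight[j])
    addPlane(i, c(rp$normal, rp$offset))
    addPlane(j, c(-rp$normal, -rp$offset))
  }
  bb <- regionBox(tess@region)
  wall <- rbind(c(-1, 0, 0, -bb$lo[1]), c(1, 0, 0, bb$hi[1]),
                c(0, -1, 0, -bb$lo[2]), c(0, 1, 0, bb$hi[2]),
                c(0, 0, -1, -bb$lo[3]), c(0, 0, 1, bb$hi[3]))
  wall <- rbind(wall, regionPlanes(tess@region))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- do.call(rbind, planes[[i]])
    out[[i]] <- if (is.null(m)) wall else rbind(m, wall)
  }
  out
}

#' Monte-Carlo agreement between cells and nearest-site assignment
#'
#' For equal-weight sites the Laguerre diagram reduces to the Voronoi
#' diagram, so each probe point must land in the cell of its (Euclidean)
#' nearest site.  The check is geometric: the probe is tested against the
#' actual face planes of the assigned cell, independently of how the cell
#' was constructed.
#'
#' @param tess A [LaguerreTessellation-class].
#' @param probes m x 3 matrix of probe points inside the region.
#' @param tol Absolute slack (Angstrom) allowed at cell boundaries.
#' @return Fraction of probes contained in their nearest site's cell.
#' @export
probeCellAgreement <- function(tess, probes, tol = 1e-7) {
  probes <- matrix(as.numeric(as.matrix(probes)), ncol = 3)
  pos <- as.matrix(tess@sites[, c("x", "y", "z")])
  assign <- nn_index_cpp(probes, pos)
  ps <- cellPlaneSet(tess)
  counts <- vapply(ps, nrow, 1L)
  planes <- do.call(rbind, ps)
  starts <- c(0L, cumsum(counts))[seq_along(counts)]
  inside <- probe_in_cell_cpp(probes, assign, planes, starts, counts, tol)
  mean(inside)
}
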
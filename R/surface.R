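# Boundary surfaces as glued polygon complexes.
#
# Faces are glued combinatorially along shared geometric edges.  V, E, F are
# counted on the glued complex, so pinched (non-manifold) edges can be split
# into separate sheets before the Euler characteristic is read off.

newellNormal <- function(P) {
  n <- c(0, 0, 0)
  k <- nrow(P)
  for (q in seq_len(k)) {
    a <- P[q, ]; b <- P[if (q == k) 1 else q + 1, ]
    n <- n + c((a[2] - b[2]) * (a[3] + b[3]),
               (a[3] - b[3]) * (a[1] + b[1]),
               (a[1] - b[1]) * (a[2] + b[2]))
  }
  n / max(sqrt(sum(n^2)), 1e-300)
}

polyArea <- function(P) {
  s <- c(0, 0, 0)
  for (q in 2:(nrow(P) - 1)) {
    u <- P[q, ] - P[1, ]; v <- P[q + 1, ] - P[1, ]
    s <- s + c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
  }
  0.5 * sqrt(sum(s^2))
}

# Pair 2k face instances around a pinched edge into k sheets.  The wedge
# between two angularly consecutive faces is "interior" when it lies on the
# material side of the first face; faces sharing an interior wedge belong to
# the same sheet.
pairPinchedFaces <- function(verts, a, b, fids, faceList, inPts) {
  u <- verts[b, ] - verts[a, ]
  u <- u / sqrt(sum(u^2))
  e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  org <- (verts[a, ] + verts[b, ]) / 2
  k <- length(fids)
  theta <- numeric(k); nInt <- matrix(0, k, 3)
  for (q in seq_len(k)) {
    P <- verts[faceList[[fids[q]]], , drop = FALSE]
    ctr <- colMeans(P)
    w <- ctr - org; w <- w - sum(w * u) * u
    theta[q] <- atan2(sum(w * e2), sum(w * e1))
    nrm <- newellNormal(P)
    if (sum(nrm * (inPts[fids[q], ] - ctr)) < 0) nrm <- -nrm
    nInt[q, ] <- nrm
  }
  ord <- order(theta)
  pairs <- list()
  used <- rep(FALSE, k)
  for (q in seq_len(k)) {
    qa <- ord[q]; qb <- ord[if (q == k) 1 else q + 1]
    if (used[qa] || used[qb]) next
    dth <- (theta[qb] - theta[qa]) %% (2 * pi)
    thm <- theta[qa] + dth / 2
    m <- cos(thm) * e1 + sin(thm) * e2
    if (sum(m * nInt[qa, ]) > 0) {        # interior wedge: same sheet
      pairs[[length(pairs) + 1L]] <- c(fids[qa], fids[qb])
      used[qa] <- TRUE; used[qb] <- TRUE
    }
  }
  if (any(!used)) {                        # fallback: consecutive pairing
    left <- fids[ord][!used[ord]]
    for (q in seq(1, length(left) - 1, by = 2))
      pairs[[length(pairs) + 1L]] <- c(left[q], left[q + 1])
  }
  pairs
}

ufFind <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

# collapse a parent vector to its roots by pointer jumping
ufResolve <- function(parent) {
  repeat {
    p2 <- parent[parent]
    if (identical(p2, parent)) return(parent)
    parent <- p2
  }
}

# Glue a polygon soup into closed surface components.
# verts: deduplicated vertex matrix; faces: list of vertex-index cycles;
# inPts: per-face interior reference point (pinch resolution); areas: per face.
buildSurfaces <- function(verts, faces, inPts = NULL, areas = NULL,
                          pinch = c("split", "strict")) {
  pinch <- match.arg(pinch)
  nf <- length(faces)
  if (!nf) return(list())
  if (is.null(areas))
    areas <- vapply(faces, function(f) polyArea(verts[f, , drop = FALSE]), 0)
  if (is.null(inPts))
    inPts <- do.call(rbind, lapply(faces, function(f)
      colMeans(verts[f, , drop = FALSE])))
  # edge instances
  ef <- integer(0); ea <- integer(0); eb <- integer(0)
  for (f in seq_len(nf)) {
    cyc <- faces[[f]]
    k <- length(cyc)
    nxt <- c(cyc[-1], cyc[1])
    keep <- cyc != nxt
    ef <- c(ef, rep.int(f, sum(keep)))
    ea <- c(ea, pmin(cyc[keep], nxt[keep]))
    eb <- c(eb, pmax(cyc[keep], nxt[keep]))
  }
  ekey <- paste(ea, eb)
  groups <- split(seq_along(ekey), ekey)
  gluedPairs <- matrix(0L, 0, 2)
  glueA <- integer(0); glueB <- integer(0)
  nBoundary <- 0L; nPinched <- 0L
  pairList <- list()
  for (g in groups) {
    fidsHere <- ef[g]
    if (length(g) == 1L) { nBoundary <- nBoundary + 1L; next }
    if (length(g) == 2L) {
      pairList[[length(pairList) + 1L]] <- c(fidsHere, ea[g[1]], eb[g[1]])
      next
    }
    if (pinch == "strict")
      stop("non-manifold edge shared by ", length(g), " faces (vertices ",
           ea[g[1]], ", ", eb[g[1]], ")")
    nPinched <- nPinched + 1L
    prs <- pairPinchedFaces(verts, ea[g[1]], eb[g[1]], fidsHere, faces, inPts)
    for (p in prs)
      pairList[[length(pairList) + 1L]] <- c(p, ea[g[1]], eb[g[1]])
  }
  # union-find over faces
  parent <- seq_len(nf)
  for (p in pairList) {
    ra <- ufFind(parent, p[1]); rb <- ufFind(parent, p[2])
    if (ra != rb) parent[rb] <- ra
  }
  comp <- ufResolve(parent)
  # corner classes: corner = (face, vertex); glued along each edge pairing
  cornKey <- unlist(lapply(seq_len(nf), function(f) paste(f, faces[[f]])))
  cornFace <- unlist(lapply(seq_len(nf), function(f) rep.int(f, length(faces[[f]]))))
  cid <- seq_along(cornKey)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (q in seq_along(cornKey)) assign(cornKey[q], q, envir = lookup)
  cparent <- cid
  for (p in pairList) {
    for (v in c(p[3], p[4])) {
      qa <- get(paste(p[1], v), envir = lookup)
      qb <- get(paste(p[2], v), envir = lookup)
      ra <- ufFind(cparent, qa); rb <- ufFind(cparent, qb)
      if (ra != rb) cparent[rb] <- ra
    }
  }
  croot <- ufResolve(cparent)
  # per-component bookkeeping
  comps <- sort(unique(comp))
  pairFace1 <- vapply(pairList, function(p) as.integer(p[1]), 1L)
  bndFaces <- ef[unlist(groups[lengths(groups) == 1L])]
  out <- lapply(comps, function(cc) {
    inC <- comp == cc
    fIdx <- which(inC)
    E <- sum(comp[pairFace1] == cc)
    Vc <- length(unique(croot[cornFace %in% fIdx]))
    bnd <- sum(comp[bndFaces] == cc)
    new("PolygonalSurface", vertices = verts, faces = faces[fIdx],
        V = Vc, E = E + bnd, F = length(fIdx),
        area = sum(areas[fIdx]), closed = bnd == 0L,
        nonManifoldEdges = nPinched)
  })
  out[order(vapply(out, function(s) s@area, 0), decreasing = TRUE)]
}

#' @describeIn PolygonalSurface-class Compact display.
#' @param object A `PolygonalSurface`.
#' @export
setMethod("show", "PolygonalSurface", function(object) {
  cat(sprintf("PolygonalSurface: V=%d E=%d F=%d, area %.2f A^2, %s%s\n",
              object@V, object@E, object@F, object@area,
              if (object@closed) "closed" else "open (boundary edges present)",
              if (object@nonManifoldEdges)
                sprintf(", %d pinched edge(s) split", object@nonManifoldEdges) else ""))
  if (object@closed) {
    chi <- object@V - object@E + object@F
    cat(sprintf("  Euler characteristic %d, genus %g\n", chi, (2 - chi) / 2))
  }
  invisible(object)
})

#' Build closed surfaces from an explicit polygon mesh
#'
#' Glues a polygon soup (vertex matrix plus vertex-index cycles) into
#' connected surface components, counting V, E, F on the glued complex.
#'
#' @param vertices n x 3 vertex matrix.
#' @param faces List of integer vertex-index cycles.
#' @param pinch `"split"` to separate sheets at pinched (non-manifold)
#'   edges, `"strict"` to raise an error on them.
#' @return List of [PolygonalSurface-class], largest area first.
#' @export
polygonalSurfaces <- function(vertices, faces, pinch = "split", tol = 1e-6) {
  vertices <- as.matrix(vertices)
  cl <- dedup_points_cpp(vertices, tol)
  verts <- rowsum(vertices, cl) / as.vector(table(cl))
  faces <- lapply(faces, function(f) {
    ids <- cl[f]
    ids[c(TRUE, ids[-1] != ids[-length(ids)])]
  })
  buildSurfaces(verts, faces[lengths(faces) >= 3], pinch = pinch)
}

#' Boundary surface of a site cluster
#'
#' The union of Laguerre faces separating cluster sites from outside sites
#' (including region-wall faces of cluster cells, so surfaces at the region
#' boundary are closed), deduplicated geometrically and split into connected
#' components via shared edges.  The outer surface comes first (largest
#' area); further closed components bound water inclusions inside the
#' cluster.
#'
#' @param tess A [LaguerreTessellation-class].
#' @param cluster Non-empty integer site-id set (must not contain empty
#'   cells).
#' @param pinch Pinched-edge handling, see [polygonalSurfaces()].
#' @param tol Vertex deduplication tolerance (Angstrom).
#' @return List of [PolygonalSurface-class], largest area first.
#' @export
boundarySurface <- function(tess, cluster, pinch = "split", tol = 1e-6) {
  cluster <- as.integer(cluster)
  if (!length(cluster)) stop("empty cluster")
  if (length(intersect(cluster, tess@emptyCells)))
    stop("cluster contains sites with empty Laguerre cells")
  f <- tess@faces
  inA <- f$i %in% cluster
  inB <- f$j %in% cluster
  pick <- which((f$j > 0 & xor(inA, inB)) | (f$j < 0 & inA))
  if (!length(pick)) stop("cluster has no boundary faces")
  polys <- tess@facePolys[pick]
  # interior reference: position of the cluster-side site of each face
  s <- tess@sites
  inSite <- ifelse(inA[pick], f$i[pick], f$j[pick])
  inPts <- as.matrix(s[inSite, c("x", "y", "z")])
  allV <- do.call(rbind, polys)
  cl <- dedup_points_cpp(allV, tol)
  verts <- rowsum(allV, cl) / as.vector(table(cl))   # rows ordered by cluster id 1..K
  offsets <- c(0L, cumsum(vapply(polys, nrow, 1L)))
  faces <- vector("list", length(polys))
  keep <- logical(length(polys))
  for (q in seq_along(polys)) {
    ids <- cl[(offsets[q] + 1L):offsets[q + 1L]]
    ids <- ids[c(TRUE, ids[-1] != ids[-length(ids)])]
    if (length(ids) > 1 && ids[1] == ids[length(ids)]) ids <- ids[-length(ids)]
    faces[[q]] <- ids
    keep[q] <- length(unique(ids)) >= 3
  }
  buildSurfaces(verts, faces[keep], inPts = inPts[keep, , drop = FALSE],
                areas = f$area[pick][keep], pinch = pinch)
}

#' Euler characteristic and genus of a closed surface
#'
#' `chi = V - E + F` and `g = (2 - chi) / 2`.
#'
#' @param surface A [PolygonalSurface-class]; must be closed (every edge
#'   shared by exactly two faces after gluing).
#' @return One-row data.frame with `V`, `E`, `F`, `chi`, `genus`, `area`.
#' @export
surfaceGenus <- function(surface) {
  if (!surface@closed)
    stop("surface is not closed: boundary edges present")
  chi <- surface@V - surface@E + surface@F
  data.frame(V = surface@V, E = surface@E, F = surface@F,
             chi = chi, genus = (2 - chi) / 2, area = surface@area)
}

#' Genus report for named site domains
#'
#' For each named domain, extracts its boundary surface components and
#' reports V, E, F, the Euler characteristic and the genus of each; the
#' headline genus of a domain is that of its largest-area component (the
#' outer surface), with inclusion surfaces listed separately.
#'
#' @param tess A [LaguerreTessellation-class].
#' @param domains Named list of integer site-id sets.
#' @param pinch Pinched-edge handling, see [polygonalSurfaces()].
#' @return data.frame with columns `domain`, `component`, `V`, `E`, `F`,
#'   `chi`, `genus`, `area`.
#' @seealso [headlineGenus()]
#' @export
domainGenus <- function(tess, domains, pinch = "split") {
  stopifnot(is.list(domains), !is.null(names(domains)))
  out <- lapply(names(domains), function(nm) {
    surfs <- boundarySurface(tess, domains[[nm]], pinch = pinch)
    do.call(rbind, lapply(seq_along(surfs), function(q)
      cbind(domain = nm, component = q, surfaceGenus(surfs[[q]]))))
  })
  do.call(rbind, out)
}

#' @rdname domainGenus
#' @param report A data.frame from [domainGenus()].
#' @return `headlineGenus`: named numeric vector, the genus of each domain's
#'   largest-area boundary component.
#' @export
headlineGenus <- function(report) {
  vapply(split(report, report$domain), function(d)
    d$genus[which.max(d$area)], 0)
}

#' Export a surface (or tessellation cells) as an OFF polygon mesh
#'
#' @param surface A [PolygonalSurface-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeOFF <- function(surface, path) {
  used <- sort(unique(unlist(surface@faces)))
  remap <- match(seq_len(nrow(surface@vertices)), used)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", length(used), length(surface@faces)), con)
  V <- surface@vertices[used, , drop = FALSE]
  writeLines(sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
  writeLines(vapply(surface@faces, function(f)
    paste(c(length(f), remap[f] - 1L), collapse = " "), ""), con)
  invisible(path)
}
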
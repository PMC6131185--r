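#' Construct a box-shaped bounded region
#'
#' @param lo,hi Numeric length-3 vectors: lower and upper corner (Angstrom).
#' @param sites Optional n x 3 coordinate matrix; when given and `lo`/`hi`
#'   are missing, the box is fitted around the sites with `padding`.
#' @param padding Margin added on each side when auto-fitting (Angstrom).
#' @return A [BoundedRegion-class] of shape `"box"`.
#' @examples
#' boxRegion(c(0, 0, 0), c(10, 10, 10))
#' @export
boxRegion <- function(lo = NULL, hi = NULL, sites = NULL, padding = 5) {
  if (is.null(lo) || is.null(hi)) {
    if (is.null(sites)) stop("give either lo/hi or sites to fit around")
    sites <- as.matrix(sites)
    lo <- apply(sites, 2, min) - padding
    hi <- apply(sites, 2, max) + padding
  } else padding <- 0
  new("BoundedRegion", shape = "box",
      bounds = as.numeric(c(lo, hi)), padding = as.numeric(padding))
}

#' Construct a spherical bounded region
#'
#' The sphere is realised as a convex polyhedral ball: the intersection of
#' tangent half-spaces at 42 near-uniform directions (subdivided
#' icosahedron).  [regionVolume()] returns the exact volume of that
#' polytope, so tessellation volume conservation stays exact.
#'
#' @param centre Numeric length-3 centre (Angstrom).
#' @param radius Sphere radius (Angstrom).
#' @return A [BoundedRegion-class] of shape `"sphere"`.
#' @export
sphereRegion <- function(centre, radius) {
  new("BoundedRegion", shape = "sphere",
      bounds = as.numeric(c(centre, radius)), padding = 0)
}

# 42 near-uniform unit directions: icosahedron vertices + edge midpoints.
icosphereDirections <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  # edge midpoints: pairs closer than 1.1 (icosahedron edge length ~1.05)
  d <- as.matrix(dist(v))
  idx <- which(d > 0 & d < 1.2, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  mid <- (v[idx[, 1], ] + v[idx[, 2], ]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  rbind(v, mid)
}

# Extra clipping planes materialising the region (beyond the init box).
regionPlanes <- function(region) {
  if (region@shape == "box") {
    return(matrix(numeric(0), 0, 4))
  }
  ctr <- region@bounds[1:3]; r <- region@bounds[4]
  dirs <- icosphereDirections()
  cbind(dirs, as.numeric(dirs %*% ctr) + r)
}

# Bounding box used to initialise cells before extra-plane clipping.
regionBox <- function(region) {
  if (region@shape == "box") {
    list(lo = region@bounds[1:3], hi = region@bounds[4:6])
  } else {
    ctr <- region@bounds[1:3]; r <- region@bounds[4]
    list(lo = ctr - r, hi = ctr + r)
  }
}

#' Volume of a bounded region
#'
#' For a box this is the product of the edge lengths; for a sphere it is the
#' exact volume of the polyhedral ball used for clipping (slightly below
#' 4/3 pi r^3).
#'
#' @param region A [BoundedRegion-class].
#' @return Volume in Angstrom^3.
#' @export
regionVolume <- function(region) {
  bb <- regionBox(region)
  if (region@shape == "box") return(prod(bb$hi - bb$lo))
  clip_polytope_volume_cpp(bb$lo, bb$hi, regionPlanes(region), 1e-12)
}

#' Test whether points lie inside a bounded region
#'
#' @param region A [BoundedRegion-class].
#' @param pts n x 3 coordinate matrix.
#' @return Logical vector of length n.
#' @export
regionContains <- function(region, pts) {
  pts <- matrix(as.numeric(as.matrix(pts)), ncol = 3)
  bb <- regionBox(region)
  inBox <- pts[, 1] >= bb$lo[1] & pts[, 1] <= bb$hi[1] &
           pts[, 2] >= bb$lo[2] & pts[, 2] <= bb$hi[2] &
           pts[, 3] >= bb$lo[3] & pts[, 3] <= bb$hi[3]
  pl <- regionPlanes(region)
  if (nrow(pl)) {
    ok <- pts %*% t(pl[, 1:3, drop = FALSE])
    inBox & apply(sweep(ok, 2, pl[, 4], "-") <= 0, 1, all)
  } else inBox
}

#' @describeIn BoundedRegion-class Compact display.
#' @param object A `BoundedRegion`.
#' @export
setMethod("show", "BoundedRegion", function(object) {
  if (object@shape == "box") {
    b <- object@bounds
    cat(sprintf("BoundedRegion box [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] A\n",
                b[1], b[4], b[2], b[5], b[3], b[6]))
  } else {
    cat(sprintf("BoundedRegion sphere centre (%.2f, %.2f, %.2f), radius %.2f A (polyhedral)\n",
                object@bounds[1], object@bounds[2], object@bounds[3], object@bounds[4]))
  }
  invisible(object)
})
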
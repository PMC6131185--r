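#' Bounded tessellation region
#'
#' The Laguerre diagram is built inside a bounded region so that every cell is
#' a finite polytope.  An axis-aligned box is the natural choice for
#' simulation snapshots; a sphere is materialised as a polyhedral ball
#' (tangent planes at 42 near-uniform directions), so that volume
#' conservation remains exact with respect to [regionVolume()].
#'
#' @slot shape `"box"` or `"sphere"`.
#' @slot bounds For a box, `c(xlo, ylo, zlo, xhi, yhi, zhi)` in Angstrom; for
#'   a sphere, `c(cx, cy, cz, radius)`.
#' @slot padding Non-negative margin (Angstrom) that was added around the
#'   sites when the region was auto-fitted.
#' @seealso [boxRegion()], [sphereRegion()]
#' @exportClass BoundedRegion
setClass("BoundedRegion",
  representation(shape = "character", bounds = "numeric", padding = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@shape %in% c("box", "sphere"))
      msg <- c(msg, "shape must be 'box' or 'sphere'")
    if (object@shape == "box") {
      if (length(object@bounds) != 6L)
        msg <- c(msg, "box bounds must have 6 elements (xlo, ylo, zlo, xhi, yhi, zhi)")
      else if (any(object@bounds[4:6] <= object@bounds[1:3]))
        msg <- c(msg, "box upper bounds must exceed lower bounds")
    } else if (length(object@bounds) != 4L || object@bounds[4] <= 0) {
      msg <- c(msg, "sphere bounds must be c(cx, cy, cz, radius > 0)")
    }
    if (length(object@padding) != 1L || object@padding < 0)
      msg <- c(msg, "padding must be a single non-negative number")
    if (is.null(msg)) TRUE else msg
  })

#' Laguerre tessellation of a weighted site set
#'
#' Central container produced by [buildTessellation()].  Sites are rows of a
#' data frame with columns `id`, `x`, `y`, `z`, `weight` (Angstrom^2), `kind`
#' (protein/water/lipid/ion/ligand), and residue bookkeeping (`chain`,
#' `resno`, `resname`, `atom`).  Faces are stored once per unordered site
#' pair; negative `j` codes identify region walls.
#'
#' @slot sites data.frame of weighted sites (one row per site, in input order).
#' @slot region The [BoundedRegion-class] the diagram was clipped to.
#' @slot volumes Numeric vector of Laguerre cell volumes (Angstrom^3).
#' @slot faces data.frame with columns `i`, `j` (site ids, `j < 0` for region
#'   walls) and `area` (Angstrom^2).
#' @slot facePolys List of polygon matrices (one per face row, ordered
#'   vertices, 3 columns).
#' @slot adjacency Two-column integer matrix of contacting site pairs
#'   (`i < j`), i.e. the edges of the dual regular triangulation.
#' @slot emptyCells Integer ids of sites whose Laguerre cell is empty
#'   (swallowed by heavier neighbours; a legal power-diagram outcome).
#' @slot boundaryCells Integer ids of cells clipped by the region boundary.
#' @seealso [buildTessellation()], [interfaceArea()], [contactGraph()]
#' @exportClass LaguerreTessellation
setClass("LaguerreTessellation",
  representation(sites = "data.frame", region = "BoundedRegion",
                 volumes = "numeric", faces = "data.frame",
                 facePolys = "list", adjacency = "matrix",
                 emptyCells = "integer", boundaryCells = "integer"),
  validity = function(object) {
    msg <- NULL
    n <- nrow(object@sites)
    if (length(object@volumes) != n)
      msg <- c(msg, "one volume per site required")
    if (any(object@volumes < -1e-9))
      msg <- c(msg, "cell volumes must be non-negative")
    if (nrow(object@faces) != length(object@facePolys))
      msg <- c(msg, "faces and facePolys must be parallel")
    if (ncol(object@adjacency) != 2L)
      msg <- c(msg, "adjacency must be a 2-column matrix")
    if (length(object@emptyCells) && any(object@volumes[object@emptyCells] > 1e-9))
      msg <- c(msg, "empty cells must have zero volume")
    if (is.null(msg)) TRUE else msg
  })

#' Closed polygonal surface (boundary 2-complex)
#'
#' A set of planar polygonal faces glued along shared edges.  Gluing is
#' combinatorial: faces are matched edge-by-edge, so pinched (non-manifold)
#' configurations can be split into separate sheets.  `V`, `E`, `F` are
#' counted on the glued complex, from which the Euler characteristic
#' `chi = V - E + F` and genus `g = (2 - chi) / 2` follow.
#'
#' @slot vertices Deduplicated vertex coordinate matrix (may contain vertices
#'   referenced by several corner classes after pinch splitting).
#' @slot faces List of integer vertex-index cycles, one per polygon.
#' @slot V,E,F Integer counts on the glued complex.
#' @slot area Total polygon area (Angstrom^2).
#' @slot closed TRUE if every edge is shared by exactly two faces after gluing.
#' @slot nonManifoldEdges Number of pinched geometric edges that were split.
#' @seealso [boundarySurface()], [surfaceGenus()]
#' @exportClass PolygonalSurface
setClass("PolygonalSurface",
  representation(vertices = "matrix", faces = "list",
                 V = "integer", E = "integer", F = "integer",
                 area = "numeric", closed = "logical",
                 nonManifoldEdges = "integer"))

#' Census of water-network connected components
#'
#' @slot components List of integer site-id vectors, ordered by smallest
#'   member id; the main component is the most populous one.
#' @slot populations Integer populations, parallel to `components`.
#' @slot mainIndex Index of the main component in `components`.
#' @slot nInclusions Number of non-main components (water inclusions).
#' @slot popMean,popRms Mean and population rms (divide-by-n) of inclusion
#'   populations; `NA` when there is no inclusion.
#' @seealso [waterComponentCensus()]
#' @exportClass ComponentCensus
setClass("ComponentCensus",
  representation(components = "list", populations = "integer",
                 mainIndex = "integer", nInclusions = "integer",
                 popMean = "numeric", popRms = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@components) != length(object@populations))
      msg <- c(msg, "components and populations must be parallel")
    if (length(object@components) &&
        (object@mainIndex < 1L || object@mainIndex > length(object@components)))
      msg <- c(msg, "mainIndex out of range")
    if (length(object@components) &&
        object@nInclusions != length(object@components) - 1L)
      msg <- c(msg, "nInclusions must equal the number of non-main components")
    if (is.null(msg)) TRUE else msg
  })

#' A traversing water path
#'
#' An ordered chain of water sites, consecutive pairs being Laguerre
#' neighbours, from a source water to a target water.
#'
#' @slot nodes Integer site ids along the path.
#' @slot totalCost Sum of the cost potential over the path's vertices (for
#'   widest paths) or total Euclidean length (for shortest disjoint paths).
#' @slot classification `"direct"`, `"indirect"`, or `NA` before
#'   classification.
#' @slot profile data.frame with per-node `z` (membrane-axis coordinate,
#'   origin at the protein centroid) and `r` (distance to the nearest
#'   protein site), filled by [radiusProfile()].
#' @seealso [shortestDisjointPaths()], [widestPaths()]
#' @exportClass WaterPath
setClass("WaterPath",
  representation(nodes = "integer", totalCost = "numeric",
                 classification = "character", profile = "data.frame"))

#' Group membership configuration for a molecular system
#'
#' Declares how atoms are partitioned into protein / water / lipid / ion /
#' ligand groups, which residues form the plug domain, the membrane normal
#' axis and slab, and the Laguerre weight given to water oxygen.
#'
#' @slot waterNames,lipidNames,ionNames Residue names assigned to each group.
#' @slot ligandName Residue name of the ligand (`NA` if none).
#' @slot plugRange Two integers: first and last residue number of the plug
#'   domain (default 1-148).
#' @slot membraneAxis `"x"`, `"y"` or `"z"` (membrane normal).
#' @slot membraneSlab Two numbers `(z_low, z_high)` in Angstrom along the
#'   membrane axis, or `NA` to infer from the lipid extent.
#' @slot waterWeight Laguerre weight of water oxygen in Angstrom^2
#'   (default 1.48, the calibrated value; weight = squared effective radius).
#' @seealso [groupingConfig()], [prepareSites()]
#' @exportClass GroupingConfig
setClass("GroupingConfig",
  representation(waterNames = "character", lipidNames = "character",
                 ionNames = "character", ligandName = "character",
                 plugRange = "integer", membraneAxis = "character",
                 membraneSlab = "numeric", waterWeight = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@waterWeight) != 1L || object@waterWeight < 0)
      msg <- c(msg, "waterWeight must be a single non-negative number")
    if (!object@membraneAxis %in% c("x", "y", "z"))
      msg <- c(msg, "membraneAxis must be 'x', 'y' or 'z'")
    if (length(object@plugRange) != 2L)
      msg <- c(msg, "plugRange must be two residue numbers")
    if (is.null(msg)) TRUE else msg
  })

#' A molecular snapshot
#'
#' Thin container around the atom table of one PDB MODEL: one row per atom
#' with columns `serial`, `atom`, `element`, `resname`, `resno`, `chain`,
#' `x`, `y`, `z`, `occupancy`.
#'
#' @slot atoms The atom data.frame.
#' @slot label Free-text snapshot label (e.g. time in ns).
#' @seealso [readStructure()], [prepareSites()]
#' @exportClass MolecularSystem
setClass("MolecularSystem",
  representation(atoms = "data.frame", label = "character"),
  validity = function(object) {
    need <- c("serial", "atom", "element", "resname", "resno", "chain",
              "x", "y", "z", "occupancy")
    if (!all(need %in% names(object@atoms)))
      return(paste("atom table must contain columns:", paste(need, collapse = ", ")))
    if (nrow(object@atoms) &&
        !all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
      return("atom coordinates must be finite")
    TRUE
  })
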
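#' Laguerre volume of a site selection
#'
#' Sum of the Laguerre cell volumes of the selected sites (e.g. a residue
#' or a whole domain); exactly additive over disjoint selections.
#'
#' @param tess A [LaguerreTessellation-class].
#' @param ids Non-empty integer site ids.
#' @return Volume in Angstrom^3.
#' @export
domainVolume <- function(tess, ids) {
  ids <- as.integer(ids)
  if (!length(ids)) stop("selector resolves to no sites")
  sum(tess@volumes[match(ids, tess@sites$id)])
}

# snapshot-statistics helper: mean and rms (divide by n) or sample sd
snapStats <- function(x, sdType) {
  m <- mean(x)
  s <- if (sdType == "rms") sqrt(mean((x - m)^2)) else sd(x)
  c(mean = m, sd = if (length(x) > 1) s else 0)
}

#' Contact-area table of a domain with its surroundings
#'
#' For each named group pair, the Laguerre interface area is computed on
#' every snapshot of two conditions (e.g. ligand-free and complexed) and
#' summarised as mean +- deviation; the difference column is
#' `dA = A_comp - A_free` and the relative column divides by `A_p`, the
#' mean total domain surface of the *complexed* condition (the reference
#' convention; configurable via `ApCondition`).
#'
#' @param tessFree,tessComp Lists of [LaguerreTessellation-class] (>= 1
#'   snapshot each).
#' @param selectors Function mapping a tessellation to a named list of
#'   disjoint site-id sets; must contain the domain group (first element of
#'   each pair below).
#' @param pairs Named list; each element is either `c(groupA, groupB)` or
#'   `c(groupA, NA)` meaning groupA against everything else (the total
#'   domain surface).
#' @param ApPair Name of the row whose complexed-condition mean serves as
#'   the denominator `A_p` of the relative change.
#' @param ApCondition `"comp"` (default) or `"free"`.
#' @param sdType `"rms"` (population, divide by n) or `"sample"`.
#' @return data.frame with columns `pair`, `A_free`, `sd_free`, `A_comp`,
#'   `sd_comp`, `dA`, `dA_rel` (fraction of `A_p`).
#' @export
contactAreaTable <- function(tessFree, tessComp, selectors, pairs,
                             ApPair = "total", ApCondition = "comp",
                             sdType = c("rms", "sample")) {
  sdType <- match.arg(sdType)
  if (!length(tessFree) || !length(tessComp))
    stop("at least one snapshot per condition is required")
  oneCondition <- function(tessList) {
    per <- vapply(tessList, function(tess) {
      sel <- selectors(tess)
      allIds <- setdiff(tess@sites$id, tess@emptyCells)
      vapply(pairs, function(p) {
        a <- sel[[p[1]]]
        b <- if (is.na(p[2])) setdiff(allIds, a) else sel[[p[2]]]
        interfaceArea(tess, a, b)
      }, 0)
    }, numeric(length(pairs)))
    per <- matrix(per, nrow = length(pairs))
    t(apply(per, 1, snapStats, sdType = sdType))
  }
  fr <- oneCondition(tessFree)
  cm <- oneCondition(tessComp)
  Ap <- if (ApCondition == "comp") cm[match(ApPair, names(pairs)), "mean"]
        else fr[match(ApPair, names(pairs)), "mean"]
  data.frame(pair = names(pairs),
             A_free = fr[, "mean"], sd_free = fr[, "sd"],
             A_comp = cm[, "mean"], sd_comp = cm[, "sd"],
             dA = cm[, "mean"] - fr[, "mean"],
             dA_rel = (cm[, "mean"] - fr[, "mean"]) / Ap,
             row.names = NULL)
}

#' Replay contact-area difference arithmetic from given means
#'
#' The bookkeeping used in [contactAreaTable()]'s difference columns,
#' applied to externally supplied mean areas: `dA = A_comp - A_free` and
#' the relative change `dA / A_p` (in percent).
#'
#' @param Afree,Acomp Named numeric vectors of mean areas (Angstrom^2).
#' @param Ap Reference total domain surface (Angstrom^2).
#' @return data.frame with `pair`, `dA`, `dA_rel_pct`.
#' @export
contactAreaDeltas <- function(Afree, Acomp, Ap) {
  stopifnot(length(Afree) == length(Acomp))
  dA <- Acomp - Afree
  data.frame(pair = names(Acomp), dA = as.numeric(dA),
             dA_rel_pct = as.numeric(100 * dA / Ap), row.names = NULL)
}

#' Per-residue contact areas of a domain with a partner group
#'
#' For each residue of the domain, the interface area between that
#' residue's atoms and the partner group, averaged over snapshots.
#'
#' @param tessList List of [LaguerreTessellation-class].
#' @param domainSel,partnerSel Functions mapping a tessellation to integer
#'   site-id sets.
#' @return data.frame with `residue` (tag) and `A` (mean area, Angstrom^2).
#' @export
perResidueContactAreas <- function(tessList, domainSel, partnerSel) {
  per <- lapply(tessList, function(tess) {
    dom <- domainSel(tess)
    par <- partnerSel(tess)
    f <- tess@faces
    real <- f$j > 0
    iIn <- real & f$i %in% dom & f$j %in% par
    jIn <- real & f$j %in% dom & f$i %in% par
    domSite <- c(f$i[iIn], f$j[jIn])
    area <- c(f$area[iIn], f$area[jIn])
    s <- tess@sites
    tag <- paste(s$chain, s$resno, s$resname, sep = ":")[match(domSite, s$id)]
    if (!length(tag)) return(data.frame(residue = character(0), A = numeric(0)))
    aggregate(list(A = area), list(residue = tag), sum)
  })
  allRes <- unique(unlist(lapply(per, `[[`, "residue")))
  A <- vapply(allRes, function(rr)
    mean(vapply(per, function(d) {
      hit <- match(rr, d$residue)
      if (is.na(hit)) 0 else d$A[hit]
    }, 0)), 0)
  data.frame(residue = allRes, A = as.numeric(A), row.names = NULL)
}

#' Select key residues from contact-area changes
#'
#' Residues whose plug-barrel contact drops below `barrelThreshold` or
#' whose plug-water contact rises above `waterThreshold` between two
#' conditions, sorted by decreasing |dA|.
#'
#' @param deltas data.frame with columns `residue`, `dA_barrel`,
#'   `dA_water` (Angstrom^2; `A_comp - A_free` per residue).
#' @param barrelThreshold Selection threshold on `dA_barrel` (Angstrom^2).
#' @param waterThreshold Selection threshold on `dA_water` (Angstrom^2).
#' @return Character vector of selected residue tags.
#' @export
keyResidueSelection <- function(deltas, barrelThreshold = -20,
                                waterThreshold = 20) {
  hit <- deltas$dA_barrel < barrelThreshold | deltas$dA_water > waterThreshold
  sel <- deltas[hit, ]
  mag <- pmax(abs(sel$dA_barrel), abs(sel$dA_water))
  sel$residue[order(mag, decreasing = TRUE)]
}

# interfacial water molecules: those sharing >= 1 Laguerre face with a
# solute (protein, lipid or ligand) site; returns per-molecule cell volume
# (summing O and any H sites of the same residue).  Molecules whose cells
# are clipped by the region boundary are excluded: their truncated volumes
# are artifacts of the bounded region, not of the solute interface.
interfacialWaterVolumes <- function(tess) {
  s <- tess@sites
  wat <- which(s$kind == "water")
  sol <- s$id[s$kind %in% c("protein", "lipid", "ligand")]
  if (!length(wat)) stop("no water sites")
  if (!length(sol)) stop("no solute sites: interfacial layer undefined")
  a <- tess@adjacency
  watTouch <- unique(c(a[a[, 1] %in% s$id[wat] & a[, 2] %in% sol, 1],
                       a[a[, 2] %in% s$id[wat] & a[, 1] %in% sol, 2]))
  mol <- paste(s$chain, s$resno)
  touchMol <- setdiff(unique(mol[match(watTouch, s$id)]),
                      unique(mol[tess@boundaryCells]))
  keep <- wat[mol[wat] %in% touchMol]
  if (!length(keep)) stop("no interfacial waters away from the region boundary")
  vol <- rowsum(tess@volumes[keep], mol[keep])
  as.numeric(vol)
}

#' Calibrate the Laguerre water weight against an explicit-hydrogen reference
#'
#' The reference run keeps water hydrogens (all weights 0) and records the
#' mean and deviation of the per-molecule Laguerre volume of interfacial
#' waters (those sharing a face with the solute).  The production
#' representation (waters reduced to O) is then tessellated for each
#' candidate radius `r` (weight `w = r^2`) and the objective
#' `f(r) = sum_i ((vbar_i - vbar_ref)^2 + (sigma_i - sigma_ref)^2)`
#' over snapshots `i` is minimised on the grid.
#'
#' @param systems List of [MolecularSystem-class] with explicit water
#'   hydrogens (>= 1 snapshot).
#' @param rGrid Sorted positive candidate water radii (Angstrom); at least 2.
#' @param cfg A [GroupingConfig-class].
#' @param region Optional [BoundedRegion-class] shared by all snapshots
#'   (default: auto box per snapshot).
#' @param vRef,sRef Optional externally supplied reference statistics
#'   (Angstrom^3), overriding the explicit-hydrogen computation (used for
#'   self-consistency checks).
#' @param sdType `"rms"` or `"sample"`.
#' @return List: `w` (argmin weight, Angstrom^2), `r` (its radius),
#'   `objective` (data.frame `r`, `w`, `f`), `vRef`, `sRef`.
#' @export
calibrateWaterWeight <- function(systems, rGrid, cfg = groupingConfig(),
                                 region = NULL, vRef = NULL, sRef = NULL,
                                 sdType = "rms") {
  if (length(rGrid) < 2) stop("radius grid must have at least 2 points")
  if (is.unsorted(rGrid) || any(rGrid <= 0)) stop("rGrid must be sorted and positive")
  if (is.null(vRef)) {
    refVols <- unlist(lapply(systems, function(sys) {
      sites <- prepareSitesWithHydrogens(sys, cfg)
      interfacialWaterVolumes(buildTessellation(sites, region))
    }))
    vRef <- mean(refVols)
    sRef <- if (sdType == "rms") sqrt(mean((refVols - vRef)^2)) else sd(refVols)
  }
  strippedSites <- lapply(systems, function(sys) prepareSites(sys, cfg))
  f <- vapply(rGrid, function(r) {
    sum(vapply(strippedSites, function(sites) {
      sites$weight[sites$kind == "water"] <- r^2
      v <- interfacialWaterVolumes(buildTessellation(sites, region))
      vb <- mean(v)
      sg <- if (sdType == "rms") sqrt(mean((v - vb)^2)) else sd(v)
      (vb - vRef)^2 + (sg - sRef)^2
    }, 0))
  }, 0)
  best <- which.min(f)
  list(w = rGrid[best]^2, r = rGrid[best],
       objective = data.frame(r = rGrid, w = rGrid^2, f = f),
       vRef = vRef, sRef = sRef)
}

#' Principal quadratic moments of a site selection
#'
#' Eigenvalues of the position covariance about the centroid (unit masses,
#' divide by n), sorted in decreasing order; a shape descriptor in
#' Angstrom^2.
#'
#' @param tess A [LaguerreTessellation-class] (or a site data.frame).
#' @param ids Integer site ids (>= 3 sites with some spatial extent).
#' @return Named numeric vector `m1 >= m2 >= m3` (collinear selections give
#'   two near-zero moments).
#' @export
quadraticMoments <- function(tess, ids = NULL) {
  s <- if (is.data.frame(tess)) tess else tess@sites
  if (is.null(ids)) ids <- s$id
  p <- as.matrix(s[match(ids, s$id), c("x", "y", "z")])
  if (nrow(p) < 3) stop("degenerate selector: need at least 3 sites")
  p <- sweep(p, 2, colMeans(p))
  ev <- sort(eigen(crossprod(p) / nrow(p), symmetric = TRUE)$values,
             decreasing = TRUE)
  if (ev[1] < 1e-12) stop("degenerate selector: all sites coincide")
  setNames(pmax(ev, 0), c("m1", "m2", "m3"))
}
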
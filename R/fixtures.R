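#' Synthetic toy systems with known ground truth
#'
#' Deterministic, seeded generators of toy molecular systems used to test
#' every analysis on known answers without any external data: random
#' packings, hydrated slabs with drilled channels and enclosed pockets,
#' barrel-and-plug assemblies threaded by engineered water channels, torus
#' clusters, and water corridors of prescribed radius.  Waters sit on a
#' jittered cubic lattice (default spacing 2.9 Angstrom, +-0.2 jitter) so
#' that lattice neighbours are Laguerre-adjacent; "protein"/"lipid" wall
#' atoms sit on a 1.8 Angstrom lattice so that no water contact leaks
#' through a wall.
#'
#' @param kind One of `"random_packing"`, `"hydrated_slab"`, `"barrel_plug"`,
#'   `"torus_cluster"`, `"corridor"`.
#' @param seed Integer seed; the same seed reproduces the fixture exactly.
#' @param ... Parameters forwarded to the specific generator.
#' @return A list with elements `sites` (site data.frame), `system`
#'   ([MolecularSystem-class]), `region` ([BoundedRegion-class]), `cfg`
#'   ([GroupingConfig-class]) and `truth` (named list of ground-truth facts,
#'   including `solidFun`, the solid-region indicator used for voxel
#'   validation).
#' @seealso [validateGroundTruth()], [writePdb()]
#' @export
makeFixture <- function(kind, seed = 1, ...) {
  switch(kind,
         random_packing = fixtureRandomPacking(seed = seed, ...),
         hydrated_slab = fixtureHydratedSlab(seed = seed, ...),
         barrel_plug = fixtureBarrelPlug(seed = seed, ...),
         torus_cluster = fixtureTorus(seed = seed, ...),
         corridor = fixtureCorridor(seed = seed, ...),
         stop("unknown fixture kind: ", kind))
}

# jittered cubic lattice of points inside box, margin from the walls
latticePoints <- function(lo, hi, spacing, jitter, margin = 0.8) {
  gx <- seq(lo[1] + margin, hi[1] - margin, by = spacing)
  gy <- seq(lo[2] + margin, hi[2] - margin, by = spacing)
  gz <- seq(lo[3] + margin, hi[3] - margin, by = spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  if (jitter > 0)
    pts <- pts + matrix(runif(length(pts), -jitter, jitter), ncol = 3)
  pts[, 1] <- pmin(pmax(pts[, 1], lo[1] + 0.5), hi[1] - 0.5)
  pts[, 2] <- pmin(pmax(pts[, 2], lo[2] + 0.5), hi[2] - 0.5)
  pts[, 3] <- pmin(pmax(pts[, 3], lo[3] + 0.5), hi[3] - 0.5)
  pts
}

waterAtomTable <- function(pts, withHydrogens = FALSE, startRes = 1L) {
  n <- nrow(pts)
  resno <- seq_len(n) + startRes - 1L
  o <- data.frame(serial = 0L, atom = "O", element = "O", resname = "HOH",
                  resno = resno, chain = "W", x = pts[, 1], y = pts[, 2],
                  z = pts[, 3], occupancy = 1, stringsAsFactors = FALSE)
  if (!withHydrogens) return(o)
  # two H per O: random orientation, 0.957 A bond, ~104.5 deg angle
  u <- matrix(rnorm(3 * n), ncol = 3); u <- u / sqrt(rowSums(u^2))
  a <- matrix(rnorm(3 * n), ncol = 3)
  a <- a - u * rowSums(a * u); a <- a / sqrt(rowSums(a^2))
  v <- u * cos(104.5 * pi / 180) + a * sin(104.5 * pi / 180)
  h1 <- o; h1$atom <- "H1"; h1$element <- "H"
  h1[, c("x", "y", "z")] <- pts + 0.957 * u
  h2 <- o; h2$atom <- "H2"; h2$element <- "H"
  h2[, c("x", "y", "z")] <- pts + 0.957 * v
  out <- rbind(o, h1, h2)
  out[order(out$resno), ]
}

wallAtomTable <- function(pts, resname = "GLY", chain = "P", resno = NULL,
                          atom = "CA", element = "C") {
  n <- nrow(pts)
  if (is.null(resno)) resno <- seq_len(n)
  data.frame(serial = 0L, atom = atom, element = element, resname = resname,
             resno = resno, chain = chain, x = pts[, 1], y = pts[, 2],
             z = pts[, 3], occupancy = 1, stringsAsFactors = FALSE)
}

assembleFixture <- function(parts, lo, hi, cfg, truth, label) {
  atoms <- do.call(rbind, parts)
  atoms$serial <- seq_len(nrow(atoms))
  system <- molecularSystem(atoms, label = label)
  sites <- prepareSites(system, cfg)
  list(sites = sites, system = system,
       region = boxRegion(lo, hi), cfg = cfg, truth = truth)
}

#' @rdname makeFixture
#' @param n Number of sites (random packing).
#' @param box Length-3 box edge lengths (Angstrom), lower corner at origin.
#' @param minDist Minimum inter-site distance (Angstrom).
#' @param weightRange Range of uniform random weights (Angstrom^2).
#' @export
fixtureRandomPacking <- function(n = 100, box = c(20, 20, 20), minDist = 1.5,
                                 weightRange = c(0, 2), seed = 1) {
  set.seed(seed)
  lo <- c(0, 0, 0); hi <- box
  pts <- matrix(NA_real_, n, 3)
  k <- 0
  while (k < n) {
    cand <- runif(3, lo + 0.8, hi - 0.8)
    if (k == 0 || min(sqrt(colSums((t(pts[seq_len(k), , drop = FALSE]) - cand)^2))) >= minDist) {
      k <- k + 1
      pts[k, ] <- cand
    }
  }
  w <- runif(n, weightRange[1], weightRange[2])
  sites <- weightedSites(pts, weight = w, kind = "water", chain = "W",
                         resname = "HOH", atom = "O")
  list(sites = sites, system = NULL, region = boxRegion(lo, hi),
       cfg = groupingConfig(), truth = list(n = n))
}

#' @rdname makeFixture
#' @param slab Length-2 z-range of the solid slab (Angstrom).
#' @param channels Number of vertical channels drilled through the solid.
#' @param channelRadius Channel radius (Angstrom).
#' @param pockets Number of one-water cavities enclosed inside the solid.
#' @param withHydrogens Give each water explicit H1/H2 atoms (calibration
#'   reference fixtures).
#' @export
fixtureHydratedSlab <- function(box = c(22, 22, 30), slab = c(12, 18),
                                channels = 0, channelRadius = 3, pockets = 0,
                                withHydrogens = FALSE, seed = 1) {
  set.seed(seed)
  lo <- c(0, 0, 0); hi <- box
  centres <- channelCentres(channels, box)
  pocketCtr <- pocketCentres(pockets, box, slab, centres, channelRadius)
  inChannel <- function(p) {
    if (!channels) return(rep(FALSE, nrow(p)))
    hit <- rep(FALSE, nrow(p))
    for (k in seq_len(channels))
      hit <- hit | sqrt((p[, 1] - centres[k, 1])^2 + (p[, 2] - centres[k, 2])^2) < channelRadius
    hit
  }
  inPocket <- function(p, r = 2.3) {
    hit <- rep(FALSE, nrow(p))
    for (k in seq_len(pockets))
      hit <- hit | sqrt(rowSums(sweep(p, 2, pocketCtr[k, ])^2)) < r
    hit
  }
  solidFun <- function(p) p[, 3] >= slab[1] & p[, 3] <= slab[2] &
    !inChannel(p) & !inPocket(p)
  wallLattice <- latticePoints(lo, hi, 1.8, 0.08)
  wallKeep <- solidFun(wallLattice) & wallLattice[, 3] >= slab[1] + 0.4 &
    wallLattice[, 3] <= slab[2] - 0.4
  wall <- wallLattice[wallKeep, ]
  wallResno <- which(wallKeep)           # stable under carving
  wat <- latticePoints(lo, hi, 2.9, 0.2)
  keep <- !solidFun(wat) &
    (wat[, 3] < slab[1] - 1.2 | wat[, 3] > slab[2] + 1.2 | inChannel(wat) | inPocket(wat, 1.0))
  wat <- wat[keep, ]
  # guarantee a connected axial water chain through each channel
  for (k in seq_len(channels)) {
    zz <- seq(slab[1] - 2.2, slab[2] + 2.2, by = 2.2)
    chain <- cbind(centres[k, 1], centres[k, 2], zz)
    near <- sqrt((wat[, 1] - centres[k, 1])^2 + (wat[, 2] - centres[k, 2])^2) < channelRadius &
      wat[, 3] > slab[1] - 2.5 & wat[, 3] < slab[2] + 2.5
    wat <- rbind(wat[!near, ], chain)
  }
  # pocket waters exactly at the cavity centres
  if (pockets > 0) {
    nearP <- inPocket(wat, 2.3)
    wat <- rbind(wat[!nearP, ], pocketCtr)
  }
  if (withHydrogens) {       # keep O-H bonds inside the region
    m <- 1.1
    wat <- wat[wat[, 1] > m & wat[, 1] < box[1] - m &
               wat[, 2] > m & wat[, 2] < box[2] - m &
               wat[, 3] > m & wat[, 3] < box[3] - m, ]
  }
  cfg <- groupingConfig(membraneSlab = slab)
  parts <- list(wallAtomTable(wall, resno = wallResno),
                waterAtomTable(wat, withHydrogens))
  truth <- list(kind = "hydrated_slab", slab = slab, channels = channels,
                channelCentres = centres, channelRadius = channelRadius,
                pockets = pockets, pocketCentres = pocketCtr,
                genus = channels, mainTraverses = channels > 0,
                inclusions = pockets + if (channels == 0) 1L else 0L,
                solidFun = solidFun, box = box)
  assembleFixture(parts, lo, hi, cfg, truth, sprintf("hydrated_slab_s%d", seed))
}

channelCentres <- function(channels, box) {
  if (!channels) return(matrix(numeric(0), 0, 2))
  frac <- list(c(0.5, 0.5), c(0.25, 0.25), c(0.75, 0.75), c(0.25, 0.75),
               c(0.75, 0.25))[seq_len(channels)]
  do.call(rbind, lapply(frac, function(f) c(f[1] * box[1], f[2] * box[2])))
}

pocketCentres <- function(pockets, box, slab, centres, channelRadius) {
  if (!pockets) return(matrix(numeric(0), 0, 3))
  zmid <- mean(slab)
  frac <- list(c(0.15, 0.6), c(0.6, 0.15), c(0.85, 0.55), c(0.4, 0.85),
               c(0.15, 0.15))[seq_len(pockets)]
  out <- do.call(rbind, lapply(frac, function(f)
    c(f[1] * box[1], f[2] * box[2], zmid)))
  out
}

#' @rdname makeFixture
#' @param barrelRadius Outer barrel radius (Angstrom).
#' @param plugRadius Radius of the solid plug filling the barrel.
#' @param withLigand Place a small ligand cluster (resname ENT) just above
#'   the plug.
#' @export
fixtureBarrelPlug <- function(channels = 2, channelRadius = 2.2,
                              barrelRadius = 13, plugRadius = 4.5,
                              box = c(36, 36, 36), slab = c(12, 24),
                              withLigand = FALSE, seed = 1) {
  if (channelRadius >= barrelRadius)
    stop("infeasible geometry: channel radius must be below the barrel radius")
  set.seed(seed)
  lo <- c(0, 0, 0); hi <- box
  ctr <- box[1:2] / 2
  # channel axes on a ring through the annulus between plug and barrel wall,
  # so the plug itself stays globular
  ring <- (plugRadius + barrelRadius) / 2
  axes <- if (channels > 0) {
    th <- 2 * pi * (seq_len(channels) - 1) / max(channels, 1)
    cbind(ctr[1] + ring * cos(th), ctr[2] + ring * sin(th))
  } else matrix(numeric(0), 0, 2)
  inChannel <- function(p) {
    hit <- rep(FALSE, nrow(p))
    for (k in seq_len(channels))
      hit <- hit | sqrt((p[, 1] - axes[k, 1])^2 + (p[, 2] - axes[k, 2])^2) < channelRadius
    hit
  }
  rho <- function(p) sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  inSlabZ <- function(p) p[, 3] >= slab[1] & p[, 3] <= slab[2]
  proteinFun <- function(p) inSlabZ(p) & rho(p) <= barrelRadius & !inChannel(p)
  lipidFun <- function(p) inSlabZ(p) & rho(p) > barrelRadius
  wall <- latticePoints(lo, hi, 1.8, 0.08)
  wall <- wall[wall[, 3] >= slab[1] + 0.4 & wall[, 3] <= slab[2] - 0.4, ]
  prot <- wall[proteinFun(wall), , drop = FALSE]
  lip <- wall[lipidFun(wall), , drop = FALSE]
  plug <- rho(prot) <= plugRadius
  resno <- integer(nrow(prot))
  resno[plug] <- ((which(plug) - 1L) %% 148L) + 1L
  resno[!plug] <- 200L + ((which(!plug) - 1L) %% 400L)
  wat <- latticePoints(lo, hi, 2.9, 0.2)
  keep <- !proteinFun(wat) & !lipidFun(wat) &
    (wat[, 3] < slab[1] - 1.2 | wat[, 3] > slab[2] + 1.2)
  wat <- wat[keep, ]
  for (k in seq_len(channels)) {
    zz <- seq(slab[1] - 2.2, slab[2] + 2.2, by = 2.2)
    chain <- cbind(axes[k, 1], axes[k, 2], zz)
    wat <- rbind(wat, chain)
  }
  parts <- list(
    wallAtomTable(prot, resname = "GLY", chain = "A", resno = resno),
    wallAtomTable(lip, resname = "DMP", chain = "L",
                  resno = seq_len(nrow(lip)), atom = "C1"),
    waterAtomTable(wat))
  if (withLigand) {
    lig <- rbind(c(0, 0, 0), c(1.6, 0, 0), c(0, 1.6, 0), c(0, 0, 1.6),
                 c(-1.6, 0, 0), c(0, -1.6, 0))
    lig <- sweep(lig, 2, c(ctr, slab[2] - 2.5), "+")
    parts <- c(parts, list(wallAtomTable(lig, resname = "ENT", chain = "E",
                                         resno = rep(900L, nrow(lig)), atom = "C")))
  }
  cfg <- groupingConfig(membraneSlab = slab,
                        ligandName = if (withLigand) "ENT" else NA_character_)
  truth <- list(kind = "barrel_plug", channels = channels,
                channelAxes = axes, channelRadius = channelRadius,
                slab = slab, genus = channels,
                mainTraverses = channels > 0, dp = channels,
                solidFun = proteinFun, lipidFun = lipidFun, box = box)
  assembleFixture(parts, lo, hi, cfg, truth, sprintf("barrel_plug_s%d", seed))
}

#' @rdname makeFixture
#' @param major,minor Major and minor radius of the solid torus (Angstrom).
#' @export
fixtureTorus <- function(major = 8, minor = 3, box = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(box)) box <- rep(2 * (major + minor) + 10, 3)
  lo <- c(0, 0, 0); hi <- box
  ctr <- box / 2
  solidFun <- function(p) {
    r <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
    (r - major)^2 + (p[, 3] - ctr[3])^2 <= minor^2
  }
  wall <- latticePoints(lo, hi, 1.8, 0.08)
  wall <- wall[solidFun(wall), , drop = FALSE]
  wat <- latticePoints(lo, hi, 2.9, 0.2)
  keep <- vapply(seq_len(nrow(wat)), function(i) {
    p <- wat[i, , drop = FALSE]
    r <- sqrt((p[1] - ctr[1])^2 + (p[2] - ctr[2])^2)
    (r - major)^2 + (p[3] - ctr[3])^2 > (minor + 1.4)^2
  }, TRUE)
  wat <- wat[keep, ]
  parts <- list(wallAtomTable(wall, chain = "A"), waterAtomTable(wat))
  cfg <- groupingConfig(membraneSlab = c(ctr[3] - minor, ctr[3] + minor))
  truth <- list(kind = "torus_cluster", genus = 1L, solidFun = solidFun, box = box)
  assembleFixture(parts, lo, hi, cfg, truth, sprintf("torus_s%d", seed))
}

#' @rdname makeFixture
#' @param radii Corridor radii (one vertical corridor per entry, Angstrom).
#' @export
fixtureCorridor <- function(radii = 4, box = c(26, 26, 30), slab = c(10, 20),
                            seed = 1) {
  set.seed(seed)
  lo <- c(0, 0, 0); hi <- box
  k <- length(radii)
  centres <- channelCentres(k, box)
  inCorr <- function(p, which = seq_len(k)) {
    hit <- rep(FALSE, nrow(p))
    for (q in which)
      hit <- hit | sqrt((p[, 1] - centres[q, 1])^2 + (p[, 2] - centres[q, 2])^2) < radii[q]
    hit
  }
  solidFun <- function(p) p[, 3] >= slab[1] & p[, 3] <= slab[2] & !inCorr(p)
  wall <- latticePoints(lo, hi, 1.8, 0.08)
  wall <- wall[solidFun(wall) & wall[, 3] >= slab[1] + 0.4 & wall[, 3] <= slab[2] - 0.4, ]
  wat <- latticePoints(lo, hi, 2.9, 0.2)
  keep <- !solidFun(wat) & (wat[, 3] < slab[1] - 1.2 | wat[, 3] > slab[2] + 1.2)
  wat <- wat[keep, ]
  for (q in seq_len(k)) {       # axial chain per corridor
    zz <- seq(slab[1] - 2.2, slab[2] + 2.2, by = 2.2)
    wat <- rbind(wat, cbind(centres[q, 1], centres[q, 2], zz))
  }
  parts <- list(wallAtomTable(wall), waterAtomTable(wat))
  cfg <- groupingConfig(membraneSlab = slab)
  truth <- list(kind = "corridor", radii = radii, centres = centres,
                slab = slab, solidFun = solidFun, box = box)
  assembleFixture(parts, lo, hi, cfg, truth, sprintf("corridor_s%d", seed))
}

#' Write a molecular system as a PDB file
#'
#' Column-exact ATOM records; round-trips through [readStructure()] at PDB
#' coordinate precision (10^-3 Angstrom).
#'
#' @param system A [MolecularSystem-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePdb <- function(system, path) {
  a <- system@atoms
  if (any(abs(c(a$x, a$y, a$z)) >= 10000))
    stop("coordinates exceed the PDB field width")
  name <- ifelse(nchar(a$atom) < 4, paste0(" ", formatC(a$atom, width = -3)),
                 substr(a$atom, 1, 4))
  rec <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 a$serial %% 100000L, name, substr(a$resname, 1, 3),
                 substr(a$chain, 1, 1), a$resno %% 10000L,
                 a$x, a$y, a$z, a$occupancy, 0,
                 substr(a$element, 1, 2))
  writeLines(c(rec, "END"), path)
  invisible(path)
}

# ---- voxel-grid oracles ------------------------------------------------
# Independent checks of fixture ground truth: occupancy flood fill for
# connectivity, Euler count of the voxel boundary surface for genus.

voxelGrid <- function(box, h = 0.9) {
  list(x = seq(h / 2, box[1] - h / 2, by = h),
       y = seq(h / 2, box[2] - h / 2, by = h),
       z = seq(h / 2, box[3] - h / 2, by = h))
}

voxelOccupancy <- function(solidFun, box, h = 0.9) {
  g <- voxelGrid(box, h)
  pts <- as.matrix(expand.grid(x = g$x, y = g$y, z = g$z))
  array(solidFun(pts), c(length(g$x), length(g$y), length(g$z)))
}

# 6-connected component labelling by vectorised flood fill
voxelComponents <- function(occ) {
  d <- dim(occ)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  nx <- d[1] + 2L
  nxy <- nx * (d[2] + 2L)
  off <- c(-1L, 1L, -nx, nx, -nxy, nxy)
  lab <- integer(length(p))
  cur <- 0L
  for (s in which(p)) {
    if (lab[s]) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      cand <- unique(as.vector(outer(frontier, off, `+`)))
      cand <- cand[cand >= 1L & cand <= length(p)]
      cand <- cand[p[cand] & lab[cand] == 0L]
      lab[cand] <- cur
      frontier <- cand
    }
  }
  array(lab, d + 2L)[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# Euler characteristic (V - E + F) of the boundary surface of a voxel solid
voxelSurfaceEuler <- function(occ) {
  d <- dim(occ)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  dp <- dim(p)
  M <- max(dp) + 2L
  vkey <- function(i, j, k) (as.numeric(i) * M + j) * M + k
  faceV <- list()
  idx <- which(p)
  co <- arrayInd(idx, dp)
  addFaces <- function(axis, dir) {
    nb <- co
    nb[, axis] <- nb[, axis] + dir
    open <- !p[cbind(nb[, 1], nb[, 2], nb[, 3])]
    cc <- co[open, , drop = FALSE]
    if (!nrow(cc)) return(NULL)
    # vertex grid corner (i-1..i etc.); face at +dir side along `axis`
    base <- cc - 1L
    base[, axis] <- base[, axis] + (dir + 1L) / 2L
    oth <- setdiff(1:3, axis)
    corner <- function(da, db) {
      v <- base
      v[, oth[1]] <- v[, oth[1]] + da
      v[, oth[2]] <- v[, oth[2]] + db
      vkey(v[, 1], v[, 2], v[, 3])
    }
    cbind(corner(0L, 0L), corner(1L, 0L), corner(1L, 1L), corner(0L, 1L))
  }
  F4 <- do.call(rbind, c(lapply(1:3, addFaces, dir = 1L),
                         lapply(1:3, addFaces, dir = -1L)))
  nF <- nrow(F4)
  verts <- unique(as.vector(F4))
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- unique(c(ekey(F4[, 1], F4[, 2]), ekey(F4[, 2], F4[, 3]),
                    ekey(F4[, 3], F4[, 4]), ekey(F4[, 4], F4[, 1])))
  list(V = length(verts), E = length(edges), F = nF,
       chi = length(verts) - length(edges) + nF)
}

#' Validate fixture ground truth with voxel-grid oracles
#'
#' Recomputes connectivity and genus facts of a fixture from its solid-region
#' indicator on a voxel grid, independently of the tessellation: flood fill
#' for water connectivity across the solid, and the Euler count of the voxel
#' boundary surface for the solid's genus.
#'
#' @param fixture A fixture list from [makeFixture()].
#' @param h Voxel edge (Angstrom).
#' @return Named list: `solidComponents`, `waterComponents` (6-connected
#'   counts), `waterTraverses` (does one water component touch both z faces),
#'   and `genus` (from `chi = 2 - 2g` of the solid boundary), where
#'   applicable.
#' @export
validateGroundTruth <- function(fixture, h = 0.9) {
  tr <- fixture$truth
  if (is.null(tr$solidFun)) return(list())
  occ <- voxelOccupancy(tr$solidFun, tr$box, h)
  solidLab <- voxelComponents(occ)
  waterLab <- voxelComponents(!occ)
  top <- unique(as.vector(waterLab[, , dim(waterLab)[3]]))
  bot <- unique(as.vector(waterLab[, , 1]))
  eu <- voxelSurfaceEuler(occ)
  list(solidComponents = max(solidLab),
       waterComponents = max(waterLab),
       waterTraverses = length(intersect(setdiff(top, 0L), setdiff(bot, 0L))) > 0,
       genus = (2 - eu$chi) / 2,
       euler = eu)
}
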
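test_that("the cost potential follows the distance-to-protein law", {
  cm <- costModel(dp = 0.1)
  expect_equal(costPotential(3, 0, cm), 1)            # node exactly at 3 A
  expect_equal(costPotential(6, 0, cm), (1 / 2)^6)
  expect_equal(costPotential(3, 2, cm), 1 + 2 * 30^6) # revisits are punishing
  expect_error(costModel(dp = 0))
})

test_that("effective radius subtracts the van der Waals radius, floored at 0", {
  atoms <- data.frame(serial = 1L, atom = "CA", element = "C", resname = "GLY",
                      resno = 1L, chain = "A", x = 5, y = 5, z = 5, occupancy = 1)
  wat <- data.frame(serial = 2:3, atom = "O", element = "O", resname = "HOH",
                    resno = 2:3, chain = "W", x = c(10, 5.6), y = 5, z = 5,
                    occupancy = 1)
  tess <- buildTessellation(prepareSites(molecularSystem(rbind(atoms, wat))),
                            boxRegion(c(0, 0, 0), c(12, 10, 10)))
  p <- new("WaterPath", nodes = siteSelect(tess, kind = "water"),
           totalCost = 0, classification = NA_character_,
           profile = data.frame())
  prof <- radiusProfile(tess, p)
  expect_equal(prof$r, c(5, 0.6))
  expect_equal(prof$reff, c(3.9, 0))
  expect_equal(prof$z, c(0, 0))            # in the protein centroid plane
})

test_that("greedy disjoint paths never exceed the Menger bound", {
  for (k in 1:40) {
    set.seed(k)
    n <- sample(6:12, 1)
    g <- randomNamedGraph(n, p = runif(1, 0.15, 0.4), seed = 700 + k)
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.5, 2)
    src <- as.character(1:2)
    tgt <- as.character((n - 1):n)
    dp <- length(hydrotopo:::greedyDisjointPaths(g, src, tgt))
    expect_lte(dp, mengerNumber(g, src, tgt))
  }
})

test_that("disjoint path counts on engineered fixtures equal the channel count", {
  for (k in 0:2) {
    fx <- fixtureHydratedSlab(channels = k, seed = 40 + k, box = c(26, 26, 30),
                              slab = c(12, 18))
    tess <- buildTessellation(fx$sites, fx$region)
    res <- shortestDisjointPaths(tess, pathRegions(tess, fx$cfg))
    expect_equal(res$census$DP, k)
    if (k == 0) expect_equal(unlist(res$census), c(DP = 0L, e_chan = 0L, p_chan = 0L))
  }
})

test_that("removing water nodes never increases DP; adding never decreases it", {
  fx <- fixtureHydratedSlab(channels = 2, seed = 44, box = c(26, 26, 30),
                            slab = c(12, 18))
  tess <- buildTessellation(fx$sites, fx$region)
  rg <- pathRegions(tess, fx$cfg)
  dp0 <- shortestDisjointPaths(tess, rg)$census$DP
  # remove the waters of one channel (all waters near the first channel axis)
  s <- siteTable(tess)
  ax <- fx$truth$channelCentres[1, ]
  inCh <- s$kind == "water" &
    sqrt((s$x - ax[1])^2 + (s$y - ax[2])^2) < fx$truth$channelRadius + 0.5 &
    s$z > fx$truth$slab[1] - 2.5 & s$z < fx$truth$slab[2] + 2.5
  rg2 <- rg
  rg2$waterIds <- setdiff(rg$waterIds, s$id[inCh])
  dp1 <- shortestDisjointPaths(tess, rg2)$census$DP
  expect_lte(dp1, dp0)
  expect_equal(dp1, dp0 - 1)                  # exactly one channel blocked
})

test_that("widest-path cost equals exhaustive enumeration on small graphs", {
  for (k in 1:10) {
    tess <- makeToyWaterTess(nWater = 8, seed = 800 + k)
    s <- siteTable(tess)
    wat <- setdiff(siteSelect(tess, kind = "water"), emptyCells(tess))
    zc <- s$z[match(wat, s$id)]
    src <- wat[zc > stats::quantile(zc, 0.7)]
    tgt <- wat[zc < stats::quantile(zc, 0.3)]
    src <- setdiff(src, tgt)
    if (!length(src) || !length(tgt)) next
    regions <- list(centre = c(6, 6, 6), radius = 100, axis = 3L,
                    slab = c(-100, 100), waterIds = wat,
                    sourceIds = src, targetIds = tgt)
    got <- widestPaths(tess, regions, cost = costModel(dp = 0.1), nIter = 1)
    # independent oracle: enumerate all simple paths and sum the potential
    g <- contactGraph(tess, wat)
    prot <- as.matrix(s[s$kind == "protein", c("x", "y", "z")])
    d <- hydrotopo:::nn_dist_cpp(as.matrix(s[match(wat, s$id), c("x", "y", "z")]), prot)
    phi <- setNames((3 / d)^6, as.character(wat))
    want <- exhaustiveMinVertexCost(g, phi, as.character(src), as.character(tgt))
    if (!length(got)) {
      expect_identical(want, Inf)
    } else {
      expect_equal(got[[1]]@totalCost, want, tolerance = 1e-10)
    }
  }
})

test_that("two-corridor search ranks the wide corridor first, then the narrow", {
  fx <- fixtureCorridor(radii = c(4, 2.2), seed = 5)
  tess <- buildTessellation(fx$sites, fx$region)
  rg <- pathRegions(tess, fx$cfg)
  wps <- widestPaths(tess, rg, cost = costModel(dp = 0.1), nIter = 3)
  expect_gte(length(wps), 2)
  costs <- vapply(wps, function(p) p@totalCost, 0)
  expect_true(all(diff(costs) >= -1e-9))      # non-decreasing costs
  # strict penalty: no node reuse
  expect_equal(anyDuplicated(unlist(lapply(wps, pathNodes))), 0)
  # the first path hugs the wide corridor axis, the second the narrow one
  s <- siteTable(tess)
  axisDist <- function(p, q) {
    xy <- s[match(pathNodes(p), s$id), c("x", "y", "z")]
    mid <- xy[xy$z > fx$truth$slab[1] & xy$z < fx$truth$slab[2], ]
    mean(sqrt((mid$x - fx$truth$centres[q, 1])^2 +
              (mid$y - fx$truth$centres[q, 2])^2))
  }
  expect_lt(axisDist(wps[[1]], 1), 1.5)
  expect_lt(axisDist(wps[[2]], 2), 1.5)
  expect_true(all(vapply(wps[1:2], function(p) p@classification, "") == "direct"))
})

test_that("soft overlap penalty traces bundles with multiplicity >= 2", {
  fx <- fixtureCorridor(radii = c(4, 2.2), seed = 5)
  tess <- buildTessellation(fx$sites, fx$region)
  rg <- pathRegions(tess, fx$cfg)
  wps <- widestPaths(tess, rg, cost = costModel(dp = 1), nIter = 10)
  expect_gte(length(wps), 3)
  costs <- vapply(wps, function(p) p@totalCost, 0)
  expect_true(all(diff(costs) >= -1e-9))
  nodeUse <- table(unlist(lapply(wps, pathNodes)))
  expect_gte(max(nodeUse), 2)                 # bottleneck localisation
  # both corridors are traced
  s <- siteTable(tess)
  usedXY <- s[match(as.integer(names(nodeUse)), s$id), c("x", "y", "z")]
  mid <- usedXY[usedXY$z > fx$truth$slab[1] & usedXY$z < fx$truth$slab[2], ]
  d1 <- sqrt((mid$x - fx$truth$centres[1, 1])^2 + (mid$y - fx$truth$centres[1, 2])^2)
  d2 <- sqrt((mid$x - fx$truth$centres[2, 1])^2 + (mid$y - fx$truth$centres[2, 2])^2)
  expect_true(any(d1 < 2) && any(d2 < 2))
})

test_that("single-corridor widest path follows the corridor axis", {
  fx <- fixtureCorridor(radii = 3.5, seed = 6)
  tess <- buildTessellation(fx$sites, fx$region)
  rg <- pathRegions(tess, fx$cfg)
  wps <- widestPaths(tess, rg, cost = costModel(dp = 0.1), nIter = 1)
  expect_length(wps, 1)
  s <- siteTable(tess)
  xy <- s[match(pathNodes(wps[[1]]), s$id), c("x", "y", "z")]
  mid <- xy[xy$z > fx$truth$slab[1] & xy$z < fx$truth$slab[2], ]
  off <- sqrt((mid$x - fx$truth$centres[1, 1])^2 + (mid$y - fx$truth$centres[1, 2])^2)
  expect_true(all(off < 2.9))                 # within one lattice spacing
  # the corridor radius is recovered by the profile
  prof <- radiusProfile(tess, wps[[1]])
  inWall <- prof$z > fx$truth$slab[1] - mean(s$z[s$kind == "protein"]) &
            prof$z < fx$truth$slab[2] - mean(s$z[s$kind == "protein"])
  expect_lt(abs(mean(prof$r[inWall]) - fx$truth$radii[1]), 0.5)
})

test_that("path classification distinguishes direct from detouring routes", {
  fx <- fixtureCorridor(radii = 3.5, seed = 7)
  tess <- buildTessellation(fx$sites, fx$region)
  rg <- pathRegions(tess, fx$cfg)
  wps <- widestPaths(tess, rg, cost = costModel(dp = 0.1), nIter = 1)
  expect_identical(wps[[1]]@classification, "direct")
  # a synthetic path with an interior node outside the augmented sphere
  s <- siteTable(tess)
  wat <- siteSelect(tess, kind = "water")
  dists <- sqrt(colSums((t(as.matrix(s[match(wat, s$id), c("x", "y", "z")])) -
                           rg$centre)^2))
  outside <- wat[which.max(dists)]
  expect_gt(max(dists), rg$radius)
  nodes <- pathNodes(wps[[1]])
  fake <- new("WaterPath",
              nodes = c(nodes[1:3], outside, nodes[4:length(nodes)]),
              totalCost = 0, classification = NA_character_,
              profile = data.frame())
  expect_identical(classifyPath(fake, rg, tess), "indirect")
})

test_that("opening census clusters nearby entries into one opening", {
  fx <- fixtureHydratedSlab(channels = 2, seed = 3)   # axes ~7.8 A apart
  tess <- buildTessellation(fx$sites, fx$region)
  rg <- pathRegions(tess, fx$cfg)
  res <- shortestDisjointPaths(tess, rg)
  expect_equal(res$census$DP, 2)
  d <- sqrt(sum((fx$truth$channelCentres[1, ] - fx$truth$channelCentres[2, ])^2))
  expect_equal(res$census$e_chan, 2)                  # axes further than 6 A
  wide <- openingCensus(res$paths, rg, tess, dOpen = d + 3)
  expect_equal(wide$e_chan, 1)                        # one merged opening
  expect_identical(unlist(openingCensus(list(), rg, tess)),
                   c(DP = 0L, e_chan = 0L, p_chan = 0L))
})

test_that("the ligand contact envelope defines water path sources", {
  fx <- fixtureBarrelPlug(channels = 2, seed = 2, withLigand = TRUE)
  tess <- buildTessellation(fx$sites, fx$region)
  env1 <- ligandContactEnvelope(list(tess))
  expect_gt(length(env1), 0)
  # identical snapshots: intersection is a no-op
  expect_setequal(ligandContactEnvelope(list(tess, tess)), env1)
  # a second snapshot restricts the envelope to shared contacts
  fx2 <- fixtureBarrelPlug(channels = 2, seed = 21, withLigand = TRUE)
  tess2 <- buildTessellation(fx2$sites, fx2$region)
  both <- ligandContactEnvelope(list(tess, tess2))
  expect_true(all(both %in% env1))
  src <- envelopeWaterSources(tess, env1)
  expect_true(all(src %in% siteSelect(tess, kind = "water")))
  expect_error(ligandContactEnvelope(list()), "no snapshots")
})
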
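test_that("radical plane position matches the analytic solution", {
  # equal weights: perpendicular bisector
  expect_equal(radicalPlane(c(0, 0, 0), 0, c(2, 0, 0), 0)$t, 1)
  # w1 = 0, w2 = 1.48: plane at x = (4 - 1.48) / 4 = 0.63
  rp <- radicalPlane(c(0, 0, 0), 0, c(2, 0, 0), 1.48)
  expect_equal(rp$t, 0.63)
  s <- weightedSites(rbind(c(0, 0, 0), c(2, 0, 0)), weight = c(0, 1.48))
  tess <- buildTessellation(s, boxRegion(c(-4, -4, -4), c(6, 4, 4)))
  f <- faceTable(tess)
  poly <- tess@facePolys[[which(f$i == 1 & f$j == 2)]]
  expect_true(all(abs(poly[, 1] - 0.63) < 1e-9))
  # cross-section area of the box at the radical plane
  expect_equal(interfaceArea(tess, 1L, 2L), 8 * 8, tolerance = 1e-9)
})

test_that("two equal-weight sites split the box symmetrically", {
  s <- weightedSites(rbind(c(-1, 0, 0), c(1, 0, 0)))
  tess <- buildTessellation(s, boxRegion(c(-4, -4, -4), c(4, 4, 4)))
  v <- cellVolumes(tess)
  expect_equal(unname(v[1]), unname(v[2]))
  expect_equal(sum(v), 8^3, tolerance = 1e-12)
})

test_that("volume is conserved on random weighted packings", {
  set.seed(42)
  for (k in 1:20) {
    n <- sample(10:200, 1)
    fx <- fixtureRandomPacking(n = n, seed = k)
    tess <- buildTessellation(fx$sites, fx$region)
    expect_lt(abs(sum(cellVolumes(tess)) - regionVolume(fx$region)) /
                regionVolume(fx$region), 1e-6)
  }
})

test_that("unit-cube corner sites are mutually adjacent along all 12 edges", {
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  s <- weightedSites(corners)
  tess <- buildTessellation(s, boxRegion(c(-5, -5, -5), c(6, 6, 6)))
  adj <- adjacencyPairs(tess)
  nn <- which(as.matrix(dist(corners)) == 1, arr.ind = TRUE)
  nn <- nn[nn[, 1] < nn[, 2], ]
  for (q in seq_len(nrow(nn)))
    expect_true(any(adj[, 1] == nn[q, 1] & adj[, 2] == nn[q, 2]),
                label = paste("edge", nn[q, 1], nn[q, 2], "present"))
  expect_lt(abs(sum(cellVolumes(tess)) - 11^3) / 11^3, 1e-6)
})

test_that("equal-weight cells agree with nearest-site Monte-Carlo membership", {
  fx <- fixtureRandomPacking(n = 120, seed = 5, weightRange = c(0, 0))
  tess <- buildTessellation(fx$sites, fx$region)
  set.seed(9)
  probes <- matrix(runif(3e4, 0.01, 19.99), ncol = 3)
  expect_gte(probeCellAgreement(tess, probes), 0.999)
})

test_that("interface areas are symmetric and additive over disjoint groups", {
  fx <- fixtureRandomPacking(n = 50, seed = 11)
  tess <- buildTessellation(fx$sites, fx$region)
  ids <- siteTable(tess)$id
  A <- ids[1:15]; B <- ids[16:30]; C <- ids[31:45]
  expect_equal(interfaceArea(tess, A, B), interfaceArea(tess, B, A))
  expect_equal(interfaceArea(tess, A, B) + interfaceArea(tess, A, C),
               interfaceArea(tess, A, c(B, C)), tolerance = 1e-9)
  expect_identical(interfaceArea(tess, A, integer(0)), 0)
  expect_error(interfaceArea(tess, A, A), "disjoint")
})

test_that("increasing one site's weight never shrinks its cell", {
  for (k in 1:5) {
    fx <- fixtureRandomPacking(n = 40, seed = 20 + k)
    t0 <- buildTessellation(fx$sites, fx$region)
    s2 <- fx$sites
    s2$weight[7] <- s2$weight[7] + 1.5
    t1 <- suppressMessages(buildTessellation(s2, fx$region))
    expect_gte(cellVolumes(t1)[7] - cellVolumes(t0)[7], -1e-9)
  }
})

test_that("volumes and areas are invariant under rigid motions", {
  # box region: translation plus an axis-aligned quarter turn is exact
  fx <- fixtureRandomPacking(n = 30, seed = 31, box = c(10, 10, 10))
  t0 <- buildTessellation(fx$sites, fx$region)
  pos <- as.matrix(fx$sites[, c("x", "y", "z")])
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  shift <- c(3, -2, 5)
  pos2 <- sweep(sweep(pos, 2, c(5, 5, 5)) %*% t(Rz), 2, c(5, 5, 5) + shift, "+")
  s2 <- fx$sites; s2[, c("x", "y", "z")] <- pos2
  t1 <- buildTessellation(s2, boxRegion(c(0, 0, 0) + shift, c(10, 10, 10) + shift))
  expect_equal(cellVolumes(t1), cellVolumes(t0), tolerance = 1e-8)
  expect_equal(interfaceArea(t1, 1:10, 11:20),
               interfaceArea(t0, 1:10, 11:20), tolerance = 1e-8)
  # arbitrary rotation inside a spherical region: interior (unclipped) cells
  # are invariant; boundary cells depend on the polyhedral-ball facets
  reg <- sphereRegion(c(5, 5, 5), 12)
  ts0 <- buildTessellation(fx$sites, reg)
  th <- 0.7
  Ra <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pos3 <- sweep(sweep(pos, 2, c(5, 5, 5)) %*% t(Ra), 2, c(5, 5, 5), "+")
  s3 <- fx$sites; s3[, c("x", "y", "z")] <- pos3
  ts1 <- buildTessellation(s3, reg)
  interior <- setdiff(fx$sites$id, union(boundaryCells(ts0), boundaryCells(ts1)))
  expect_gt(length(interior), 5)
  expect_equal(cellVolumes(ts1)[interior], cellVolumes(ts0)[interior],
               tolerance = 1e-8)
})

test_that("swallowed sites yield flagged empty cells, not crashes", {
  # a light site between two heavy ones: its power cell vanishes
  s <- weightedSites(rbind(c(5, 10, 10), c(10, 10, 10), c(15, 10, 10)),
                     weight = c(30, 0, 30))
  expect_message(tess <- buildTessellation(s, boxRegion(c(0, 0, 0), c(20, 20, 20))),
                 "empty Laguerre cell")
  expect_identical(emptyCells(tess), 2L)
  expect_equal(unname(cellVolumes(tess)[2]), 0)
  expect_false(any(adjacencyPairs(tess) == 2L))
  expect_lt(abs(sum(cellVolumes(tess)) - 8000) / 8000, 1e-6)
})

test_that("invalid inputs are rejected with explicit errors", {
  expect_error(buildTessellation(weightedSites(rbind(c(1, 1, 1)))), "2 sites")
  dup <- weightedSites(rbind(c(1, 1, 1), c(1, 1, 1)), weight = 0.5)
  expect_error(buildTessellation(dup, boxRegion(c(0, 0, 0), c(2, 2, 2))),
               "coincident")
  out <- weightedSites(rbind(c(1, 1, 1), c(9, 9, 9)))
  expect_error(buildTessellation(out, boxRegion(c(0, 0, 0), c(5, 5, 5))),
               "inside the region")
})

test_that("coplanar site sets tessellate into exact prisms", {
  # all sites in the z = 5 plane: cells are vertical prisms over 2D cells
  set.seed(3)
  pos <- cbind(runif(20, 1, 9), runif(20, 1, 9), 5)
  tess <- buildTessellation(weightedSites(pos), boxRegion(c(0, 0, 0), c(10, 10, 10)))
  expect_lt(abs(sum(cellVolumes(tess)) - 1000) / 1000, 1e-6)
})

test_that("wall clipping and ghost mirroring give identical box tessellations", {
  fx <- fixtureRandomPacking(n = 60, seed = 55)
  tClip <- buildTessellation(fx$sites, fx$region, boundary = "clip")
  tMirror <- buildTessellation(fx$sites, fx$region, boundary = "mirror")
  expect_equal(cellVolumes(tMirror), cellVolumes(tClip), tolerance = 1e-9)
  pairKey <- function(t) sort(paste(adjacencyPairs(t)[, 1], adjacencyPairs(t)[, 2]))
  expect_identical(pairKey(tMirror), pairKey(tClip))
  expect_setequal(boundaryCells(tMirror), boundaryCells(tClip))
  expect_error(buildTessellation(fx$sites, sphereRegion(c(10, 10, 10), 30),
                                 boundary = "mirror"), "box regions")
})

test_that("a linear water chain produces a path contact graph", {
  z <- seq(0, by = 2.8, length.out = 5)
  s <- weightedSites(cbind(10, 10, 10 + z), weight = 1.48, kind = "water")
  tess <- buildTessellation(s, boxRegion(c(0, 0, 0), c(20, 20, 35)))
  g <- contactGraph(tess)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  deg <- igraph::degree(g)
  expect_equal(sort(unname(deg)), c(1, 1, 2, 2, 2))
  # single-vertex subset: 1 vertex, no edges
  g1 <- contactGraph(tess, 3L)
  expect_equal(igraph::vcount(g1), 1)
  expect_equal(igraph::ecount(g1), 0)
  # duality: full-set edge count equals the number of site-site faces
  expect_equal(igraph::ecount(contactGraph(tess)),
               sum(faceTable(tess)$j > 0))
})
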
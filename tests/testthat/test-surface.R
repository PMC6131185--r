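cubeMesh <- function(origin = c(0, 0, 0), edge = 1, offset = 0L) {
  V <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * edge
  V <- sweep(V, 2, origin, "+")
  # faces as vertex cycles (1-based into V)
  F <- list(c(1, 3, 4, 2), c(5, 6, 8, 7), c(1, 2, 6, 5),
            c(3, 7, 8, 4), c(1, 5, 7, 3), c(2, 4, 8, 6))
  list(V = V, F = lapply(F, function(f) f + offset))
}

torusMesh <- function(nu = 8, nv = 8, R = 10, r = 3, triangulate = TRUE) {
  iu <- rep(0:(nu - 1), each = nv); iv <- rep(0:(nv - 1), nu)
  th <- 2 * pi * iu / nu; ph <- 2 * pi * iv / nv
  V <- cbind((R + r * cos(ph)) * cos(th), (R + r * cos(ph)) * sin(th),
             r * sin(ph))
  vid <- function(i, j) ((i %% nu) * nv + (j %% nv)) + 1
  F <- list()
  for (i in 0:(nu - 1)) for (j in 0:(nv - 1)) {
    q <- c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1), vid(i, j + 1))
    if (triangulate) {
      F[[length(F) + 1]] <- q[c(1, 2, 3)]
      F[[length(F) + 1]] <- q[c(1, 3, 4)]
    } else F[[length(F) + 1]] <- q
  }
  list(V = V, F = F)
}

test_that("cube and torus meshes have the textbook Euler counts", {
  cm <- cubeMesh()
  s <- polygonalSurfaces(cm$V, cm$F)
  expect_length(s, 1)
  g <- surfaceGenus(s[[1]])
  expect_equal(g[, c("V", "E", "F", "chi", "genus")],
               data.frame(V = 8L, E = 12L, F = 6L, chi = 2L, genus = 0))

  tm <- torusMesh()
  st <- polygonalSurfaces(tm$V, tm$F)
  expect_length(st, 1)
  gt <- surfaceGenus(st[[1]])
  expect_equal(gt[, c("V", "E", "F", "chi", "genus")],
               data.frame(V = 64L, E = 192L, F = 128L, chi = 0L, genus = 1))

  # Euler characteristic is invariant under quad/triangle subdivision
  tq <- torusMesh(triangulate = FALSE)
  expect_equal(surfaceGenus(polygonalSurfaces(tq$V, tq$F)[[1]])$chi, 0)
})

test_that("disjoint closed meshes split into genus-0 components", {
  c1 <- cubeMesh(c(0, 0, 0))
  c2 <- cubeMesh(c(5, 5, 5), offset = 8L)
  s <- polygonalSurfaces(rbind(c1$V, c2$V), c(c1$F, c2$F))
  expect_length(s, 2)
  expect_equal(surfaceGenus(s[[1]])$genus, 0)
  expect_equal(surfaceGenus(s[[2]])$genus, 0)
})

test_that("open meshes are rejected by the genus computation", {
  cm <- cubeMesh()
  s <- polygonalSurfaces(cm$V, cm$F[-1])     # remove one face
  expect_false(s[[1]]@closed)
  expect_error(surfaceGenus(s[[1]]), "not closed")
})

test_that("pinched meshes raise in strict mode", {
  # two cubes sharing one edge (diagonal neighbours): 4 faces meet there
  c1 <- cubeMesh(c(0, 0, 0))
  c2 <- cubeMesh(c(1, 1, 0), offset = 8L)
  V <- rbind(c1$V, c2$V)
  expect_error(polygonalSurfaces(V, c(c1$F, c2$F), pinch = "strict"),
               "non-manifold")
})

test_that("a single interior cell bounds a genus-0 surface", {
  s <- weightedSites(rbind(c(5, 5, 5), c(50, 50, 50)))
  tess <- buildTessellation(s, boxRegion(c(0, 0, 0), c(60, 60, 60)))
  su <- boundarySurface(tess, 1L)
  expect_length(su, 1)
  expect_equal(surfaceGenus(su[[1]])$genus, 0)
})

test_that("a convex blob in water has one genus-0 outer surface", {
  set.seed(12)
  ctr <- c(11, 11, 11)
  pts <- as.matrix(expand.grid(seq(7, 15, 1.8), seq(7, 15, 1.8), seq(7, 15, 1.8)))
  blob <- pts[sqrt(colSums((t(pts) - ctr)^2)) <= 4.5, ]
  wat <- as.matrix(expand.grid(seq(1, 21, 2.9), seq(1, 21, 2.9), seq(1, 21, 2.9)))
  wat <- wat + matrix(runif(length(wat), -0.2, 0.2), ncol = 3)
  wat <- wat[sqrt(colSums((t(wat) - ctr)^2)) > 6.5, ]
  sites <- rbind(
    weightedSites(blob, kind = "protein", chain = "A"),
    weightedSites(wat, weight = 1.48, kind = "water", chain = "W", resname = "HOH"))
  sites$id <- seq_len(nrow(sites)); sites$resno <- seq_len(nrow(sites))
  tess <- buildTessellation(sites, boxRegion(c(0, 0, 0), c(22, 22, 22)))
  su <- boundarySurface(tess, seq_len(nrow(blob)))
  expect_length(su, 1)
  expect_equal(surfaceGenus(su[[1]])$genus, 0)
})

test_that("an enclosed water adds a second closed boundary component", {
  ctr <- c(11, 11, 11)
  pts <- as.matrix(expand.grid(seq(6.6, 15.6, 1.8), seq(6.6, 15.6, 1.8),
                               seq(6.6, 15.6, 1.8)))
  d <- sqrt(colSums((t(pts) - ctr)^2))
  blob <- pts[d <= 5.2 & d > 2.2, ]          # hollow shell
  set.seed(5)
  wat <- as.matrix(expand.grid(seq(1, 21, 2.9), seq(1, 21, 2.9), seq(1, 21, 2.9)))
  wat <- wat + matrix(runif(length(wat), -0.2, 0.2), ncol = 3)
  wat <- wat[sqrt(colSums((t(wat) - ctr)^2)) > 7, ]
  wat <- rbind(wat, ctr)                     # one trapped interior water
  sites <- rbind(
    weightedSites(blob, kind = "protein", chain = "A"),
    weightedSites(wat, weight = 1.48, kind = "water", chain = "W", resname = "HOH"))
  sites$id <- seq_len(nrow(sites)); sites$resno <- seq_len(nrow(sites))
  tess <- buildTessellation(sites, boxRegion(c(0, 0, 0), c(22, 22, 22)))
  su <- boundarySurface(tess, seq_len(nrow(blob)))
  expect_length(su, 2)                       # outer surface + inclusion surface
  expect_equal(surfaceGenus(su[[1]])$genus, 0)
  expect_equal(surfaceGenus(su[[2]])$genus, 0)
  expect_lt(su[[2]]@area, su[[1]]@area)
})

test_that("a torus-shaped cluster has headline genus 1", {
  fx <- fixtureTorus(seed = 4)
  tess <- buildTessellation(fx$sites, fx$region)
  rep <- domainGenus(tess, list(torus = siteSelect(tess, kind = "protein")))
  expect_equal(unname(headlineGenus(rep)["torus"]), 1)
})

test_that("genus is invariant under rigid motion and weight rescaling", {
  fx <- fixtureHydratedSlab(channels = 1, seed = 9, box = c(20, 20, 26),
                            slab = c(10, 16))
  t0 <- buildTessellation(fx$sites, fx$region)
  g0 <- surfaceGenus(boundarySurface(t0, siteSelect(t0, kind = "protein"))[[1]])$genus
  expect_equal(g0, 1)
  # translate everything (region included)
  s2 <- fx$sites
  s2[, c("x", "y", "z")] <- s2[, c("x", "y", "z")] + 7
  t2 <- buildTessellation(s2, boxRegion(c(7, 7, 7), c(27, 27, 33)))
  expect_equal(surfaceGenus(boundarySurface(t2, siteSelect(t2, kind = "protein"))[[1]])$genus, g0)
  # rescale the water weight (adjacency-preserving here)
  s3 <- fx$sites
  s3$weight[s3$kind == "water"] <- 1.1
  t3 <- buildTessellation(s3, fx$region)
  expect_equal(surfaceGenus(boundarySurface(t3, siteSelect(t3, kind = "protein"))[[1]])$genus, g0)
})

test_that("barrel-plug domain genera reproduce the fixture ground truth", {
  fx <- fixtureBarrelPlug(channels = 2, seed = 2)
  tess <- buildTessellation(fx$sites, fx$region)
  prot <- siteSelect(tess, kind = "protein")
  plug <- intersect(prot, siteSelect(tess, range = c(1, 148), chain = "A"))
  periph <- setdiff(prot, plug)
  rep <- domainGenus(tess, list(protein = prot, plug = plug, periphery = periph))
  hg <- headlineGenus(rep)
  expect_equal(unname(hg["protein"]), fx$truth$genus)   # one handle per channel
  expect_equal(unname(hg["plug"]), 0)                   # globular plug
  # the global genus is not the sum of the partial genera
  expect_false(hg["protein"] == hg["plug"] + hg["periphery"])
})

test_that("OFF export writes a parseable mesh", {
  cm <- cubeMesh()
  s <- polygonalSurfaces(cm$V, cm$F)[[1]]
  f <- tempfile(fileext = ".off")
  writeOFF(s, f)
  lines <- readLines(f)
  expect_identical(lines[1], "OFF")
  expect_identical(lines[2], "8 6 0")
})
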
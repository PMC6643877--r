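# Mesh surface area, 15 um disk density, density maps.

test_that("a single triangle has the closed-form area", {
  pc <- Pointcloud(coords = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                   expr = matrix(0, 3, 1, dimnames = list(NULL, "g")),
                   neighbors = list(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
  expect_equal(surfaceArea(pc), 0.5)
  expect_identical(nrow(meshTriangles(pc)), 1L)
})

test_that("mesh area of a 6000-nucleus sphere matches 4*pi*r^2 within 2%", {
  pc <- atlasPointcloud(sphereGen())
  expect_equal(surfaceArea(pc), 4 * pi * 100^2, tolerance = 0.02)
})

test_that("mesh area of a prolate ellipsoid matches the closed form", {
  gen <- smallGen() # eggLength 400, radius 80
  pc <- atlasPointcloud(gen)
  expect_equal(surfaceArea(pc), flyatlas:::.ellipsoidArea(200, 80),
               tolerance = 0.02)
})

test_that("non-manifold meshes are rejected with the offending edges", {
  # two triangles sharing edge (1,2) plus a third on the same edge
  nb <- list(c(2L, 3L, 4L, 5L), c(1L, 3L, 4L, 5L), c(1L, 2L),
             c(1L, 2L), c(1L, 2L))
  pc <- Pointcloud(coords = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                  c(0, -1, 0), c(0, 0, 1)),
                   expr = matrix(0, 5, 1, dimnames = list(NULL, "g")),
                   neighbors = nb)
  expect_error(surfaceArea(pc), "non-manifold.*\\(1,2\\)")
})

test_that("local density uses the 15 um disk and pi r^2 normalization", {
  # isolated nuclei: exactly themselves in the disk
  far <- Pointcloud(coords = rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0)),
                    expr = matrix(0, 3, 1, dimnames = list(NULL, "g")))
  expect_equal(localDensity(far), rep(1 / (pi * 225), 3))
  expect_equal(localDensity(far, includeSelf = FALSE), rep(0, 3))
  # a nucleus exactly at 15 um is inside the closed disk
  pair <- Pointcloud(coords = rbind(c(0, 0, 0), c(15, 0, 0)),
                     expr = matrix(0, 2, 1, dimnames = list(NULL, "g")))
  expect_equal(localDensity(pair), rep(2 / (pi * 15^2), 2))
})

test_that("a uniform planar grid has the lattice density", {
  s <- 5
  g <- expand.grid(x = seq(0, 100, by = s), y = seq(0, 100, by = s))
  pc <- Pointcloud(coords = cbind(g$x, g$y, 0),
                   expr = matrix(0, nrow(g), 1, dimnames = list(NULL, "g")))
  d <- localDensity(pc)
  interior <- g$x >= 20 & g$x <= 80 & g$y >= 20 & g$y <= 80
  # lattice-count oracle: points of a 5 um grid inside a closed 15 um disk
  offs <- expand.grid(i = -3:3, j = -3:3)
  inDisk <- sum(sqrt(offs$i^2 + offs$j^2) * s <= 15)
  expect_equal(mean(d[interior]), inDisk / (pi * 225), tolerance = 1e-9)
  expect_equal(mean(d[interior]), 1 / s^2, tolerance = 0.1)
})

test_that("mean density of a uniform embryo matches N/area within 5%", {
  gen <- sphereGen()
  pc <- atlasPointcloud(gen)
  expect_equal(mean(localDensity(pc)), nNuclei(pc) / surfaceArea(pc),
               tolerance = 0.05)
})

test_that("density map integrates back to the nucleus count within 10%", {
  spec <- syntheticSpec(nSpecies = 1, nNuclei = 4000L, eggLength = 400,
                        furrows = list(), seed = 4)
  es <- generateEmbryoSet(spec, 1L, 3L, 1L)
  pc <- es$embryos[[1]]
  dm <- densityMap(es$embryos, 3L, grid = c(50L, 16L))
  expect_equal(mean(dm@values) * surfaceArea(pc), nNuclei(pc),
               tolerance = 0.1)
  # uniform embryo: map approximately constant away from the poles
  mid <- dm@values[dm@ap > 0.15 & dm@ap < 0.85, ]
  expect_lt(stats::sd(mid) / mean(mid), 0.15)
})

test_that("density map recovers a known Gaussian depression location", {
  spec <- syntheticSpec(
    nSpecies = 1, nNuclei = 4000L, eggLength = 400,
    furrows = list(list(ap = 0.6, phi = pi / 2, depth = 0.6,
                        sigmaAp = 0.08, sigmaPhi = 0.6)),
    seed = 44)
  es <- generateEmbryoSet(spec, 2L, 4L, 1L)
  dm <- densityMap(es$embryos, 4L, grid = c(25L, 8L))
  ix <- which(dm@values == min(dm@values), arr.ind = TRUE)[1, ]
  expect_lte(abs(dm@ap[ix[1]] - 0.6), 1 / 25) # within one grid cell
  expect_lte(abs(flyatlas:::.wrapAngle(dm@phi[ix[2]] - pi / 2)),
             2 * pi / 8)
})

test_that("density map averaging is linear across embryos", {
  spec <- syntheticSpec(nSpecies = 1, nNuclei = 1000L, eggLength = 400,
                        furrows = list(), seed = 6)
  es <- generateEmbryoSet(spec, 2L, 2L, 1L)
  m1 <- densityMap(es$embryos[1], 2L, grid = c(20L, 8L))
  m2 <- densityMap(es$embryos[2], 2L, grid = c(20L, 8L))
  m12 <- densityMap(es$embryos, 2L, grid = c(20L, 8L))
  expect_equal(m12@values, (m1@values + m2@values) / 2)
  expect_error(densityMap(es$embryos, 5L), "no embryos in cohort")
})

test_that("surface area and egg length are rigid-motion invariant", {
  pc <- atlasPointcloud(smallGen())
  R <- rot3(0.5, c(1, -2, 2))
  moved <- Pointcloud(coords = coords(pc) %*% t(R) +
                        rep(1, nNuclei(pc)) %o% c(-4, 2, 7),
                      expr = exprValues(pc), neighbors = neighbors(pc),
                      metadata = list(dorsal = drop(R %*% c(0, 0, 1))))
  expect_equal(surfaceArea(moved), surfaceArea(pc), tolerance = 1e-9)
  expect_equal(eggLength(moved), eggLength(pc), tolerance = 1e-9)
})
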
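# Expression distance scores, spatial matching, local best-match search
# and displacement fields.

test_that("normalization scales each gene-cohort maximum to exactly 1", {
  E <- lapply(1:6, function(t) {
    cbind(a = c(2, 4, 1) * t, b = if (t == 3) c(0, 0, 0) else c(1, 2, 3))
  })
  atl <- tinyAtlas(E)
  expect_warning(n <- normalizeExpression(atl), "all-zero")
  expect_equal(unname(exprValues(n, 3)[, "a"]), c(0.5, 1, 0.25))
  expect_equal(unname(exprValues(n, 3)[, "b"]), c(0, 0, 0)) # untouched
  expect_equal(unname(exprValues(n, 5)[, "b"]), c(1, 2, 3) / 3)
})

test_that("D is symmetric, non-negative, zero iff equal, and additive", {
  x <- c(0.2, 0.9, 0.4)
  y <- c(0.7, 0.9, 0.1)
  expect_identical(expressionDistance(x, x), 0)
  expect_equal(expressionDistance(x, y), expressionDistance(y, x))
  expect_equal(expressionDistance(0.5, 1), 0.25) # 1 gene, 1 cohort
  # additive across disjoint gene blocks
  expect_equal(expressionDistance(x[1], y[1]) +
                 expressionDistance(x[2:3], y[2:3]),
               expressionDistance(x, y))
  expect_error(expressionDistance(x, y[1:2]), "length")
})

test_that("expression profiles follow cross-cohort correspondence", {
  E <- lapply(1:6, function(t) cbind(g = c(10, 20) + t))
  atl <- tinyAtlas(E)
  atl@correspondence <- rep(list(c(2L, 1L)), 5L) # swap every step
  P <- expressionProfiles(atl, cohorts = c(5, 6), anchor = 6L)
  # anchored nucleus 1 at cohort 6 was nucleus 2 at cohort 5
  expect_equal(unname(P[1, ]), c(20 + 5, 10 + 6))
  expect_equal(unname(P[2, ]), c(10 + 5, 20 + 6))
  atl@correspondence[[5]] <- c(2L, NA)
  expect_error(expressionProfiles(atl, cohorts = 5:6), "tracked")
})

test_that("an atlas matched to itself is the identity with zero distance", {
  atl <- normalizeExpression(smallGen()$atlas)
  sm <- spatialMatch(atl, atl)
  expect_identical(sm$target_index, sm$query_index)
  res <- localBestMatch(atl, atl, k = 10)
  tb <- matchTable(res)
  expect_equal(tb$spatial_dist, rep(0, nrow(tb)))
  expect_equal(tb$local_best_dist, rep(0, nrow(tb)))
})

test_that("spatial matching is invariant to rigid translation", {
  atl <- normalizeExpression(smallGen()$atlas)
  shifted <- atl
  shifted@positions <- lapply(atl@positions, function(p)
    p + rep(1, nrow(p)) %o% c(100, -50, 30))
  expect_identical(spatialMatch(atl, shifted)$target_index,
                   spatialMatch(atl, atl)$target_index)
})

test_that("local best-match equals a brute-force double loop on toys", {
  spec <- syntheticSpec(nSpecies = 2, nNuclei = c(200L, 200L),
                        eggLength = c(400, 400),
                        shiftField = c(0, 0.03), seed = 71)
  ref <- normalizeExpression(generateAtlas(spec, 1)$atlas)
  tgt <- normalizeExpression(generateAtlas(spec, 2)$atlas)
  k <- 30L
  res <- localBestMatch(ref, tgt, k = k)
  tb <- matchTable(res)
  Pr <- expressionProfiles(ref)
  Pt <- expressionProfiles(tgt)
  # independent oracle: explicit loops over query nuclei and candidates
  q <- flyatlas:::.scaledCoords(ref)
  x <- flyatlas:::.scaledCoords(tgt)
  for (i in seq(1, nrow(q), by = 7)) {
    d2 <- colSums((t(x) - q[i, ])^2)
    cand <- order(d2)[seq_len(k)]
    Ds <- vapply(cand, function(j) sum((Pr[i, ] - Pt[j, ])^2), 0)
    expect_lt(abs(tb$local_best_dist[i] - min(Ds)), 1e-10)
    expect_lt(abs(tb$spatial_dist[i] -
                    sum((Pr[i, ] - Pt[which.min(d2), ])^2)), 1e-10)
  }
  expect_true(all(tb$local_best_dist <= tb$spatial_dist))
})

test_that("weighted displacement follows the stated weighting rules", {
  pos <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  # all candidates equidistant in D -> unweighted centroid
  wd <- weightedDisplacement(rep(0.5, 4), pos, query = c(1, 1, 1), m = 4)
  expect_equal(wd$target, colMeans(pos))
  expect_equal(wd$displacement, colMeans(pos) - c(1, 1, 1))
  # a zero-D candidate short-circuits to the exact match
  wd0 <- weightedDisplacement(c(0.4, 0, 0.1, 0.2), pos, c(1, 1, 1), m = 4)
  expect_equal(wd0$target, c(2, 0, 0))
  # only the m best candidates enter
  wd2 <- weightedDisplacement(c(1, 1, 99, 99), pos, c(0, 0, 0), m = 2)
  expect_equal(wd2$target, c(1, 0, 0))
})

test_that("a known 2% egg-length shift is recovered within 0.5% EL", {
  pair <- shiftPairGen()
  ref <- normalizeExpression(pair$ref$atlas)
  tgt <- normalizeExpression(pair$target$atlas)
  res <- localBestMatch(ref, tgt, scaled = TRUE)
  dAp <- matchTable(res)$disp_x # AP axis is x for synthetic embryos
  expect_lt(abs(median(dAp) - 0.02), 0.005)
  # displacement field: pure AP shift concentrates direction along +AP
  resUm <- localBestMatch(ref, tgt)
  fld <- displacementField(resUm, ref)
  expect_equal(median(fld$d_ap), 0.02, tolerance = 0.25)
  expect_lt(median(fld$direction[abs(fld$d_ap) > 0.01]), pi / 4)
})

test_that("expression distances grow with the generated shift", {
  meds <- vapply(c(0.01, 0.02, 0.04), function(sh) {
    spec <- syntheticSpec(nSpecies = 2, nNuclei = c(1500L, 1500L),
                          eggLength = c(400, 400),
                          shiftField = c(0, sh), seed = 83)
    ref <- normalizeExpression(generateAtlas(spec, 1)$atlas)
    tgt <- normalizeExpression(generateAtlas(spec, 2)$atlas)
    median(matchTable(localBestMatch(ref, tgt))$spatial_dist)
  }, 0)
  expect_true(all(diff(meds) > 0))
})

test_that("displacement magnitudes are invariant under rigid rotation of
           both atlases", {
  spec <- syntheticSpec(nSpecies = 2, nNuclei = c(400L, 400L),
                        eggLength = c(400, 400),
                        shiftField = c(0, 0.02), seed = 91)
  ref <- normalizeExpression(generateAtlas(spec, 1)$atlas)
  tgt <- normalizeExpression(generateAtlas(spec, 2)$atlas)
  base <- matchTable(localBestMatch(ref, tgt))
  R <- rot3(0.9, c(3, 1, -2))
  spin <- function(a) {
    a@positions <- lapply(a@positions, function(p) p %*% t(R))
    a@metadata$dorsal <- drop(R %*% a@metadata$dorsal)
    a@metadata$anterior <- drop(R %*% a@metadata$anterior)
    a
  }
  got <- matchTable(localBestMatch(spin(ref), spin(tgt)))
  magBase <- sqrt(base$disp_x^2 + base$disp_y^2 + base$disp_z^2)
  magGot <- sqrt(got$disp_x^2 + got$disp_y^2 + got$disp_z^2)
  expect_equal(magGot, magBase, tolerance = 1e-6)
})

test_that("a target smaller than k is used whole, with a warning", {
  spec <- syntheticSpec(nSpecies = 1, nNuclei = 100L, eggLength = 300,
                        maxRadius = 80, seed = 3)
  atl <- normalizeExpression(generateAtlas(spec, 1)$atlas)
  expect_warning(res <- localBestMatch(atl, atl, k = 500L), "smaller than k")
  expect_identical(res@k, nNuclei(atl))
})
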
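# Cell-type profile distances, greedy monotone time matching, and the
# hourglass curve.

mkProfile <- function(P, species = "s", types = NULL,
                      universe = c("a", "b")) {
  if (is.null(types)) types <- paste0("T", seq_len(nrow(P)))
  new("CellTypeProfile", species = species, universe = universe,
      types = types, proportions = P)
}

# second, naive implementation of the greedy monotone rule (oracle)
greedyOracle <- function(M) {
  p <- integer(nrow(M))
  p[1] <- 1L
  for (t in seq_len(nrow(M))[-1]) {
    best <- NA_integer_; bestVal <- Inf
    for (j in seq_len(ncol(M))) {
      if (j >= p[t - 1] && M[t, j] < bestVal) {
        bestVal <- M[t, j]; best <- j
      }
    }
    p[t] <- best
  }
  p
}

test_that("profile distances are Euclidean with union type alignment", {
  a <- mkProfile(matrix(1, 1, 1), types = "x")
  b <- mkProfile(matrix(1, 1, 1), types = "y")
  # disjoint single types: vectors (1,0) vs (0,1) -> sqrt(2)
  dm <- profileDistanceMatrix(a, b)
  expect_equal(dm, matrix(sqrt(2), 1, 1))
  same <- mkProfile(diag(2) * 0.5, types = c("x", "y"))
  expect_equal(diag(profileDistanceMatrix(same, same)), c(0, 0))
  # transpose symmetry
  p <- mkProfile(matrix(runif(12, 0, 0.1), 2, 6), types = c("x", "y"))
  q <- mkProfile(matrix(runif(12, 0, 0.1), 2, 6), types = c("x", "y"))
  expect_equal(profileDistanceMatrix(p, q),
               t(profileDistanceMatrix(q, p)))
  bad <- mkProfile(matrix(0.1, 1, 6), types = "x", universe = c("q", "r"))
  expect_error(profileDistanceMatrix(p, bad), "universe")
})

test_that("diagonal-dominant matrices give the identity path", {
  M <- matrix(1, 6, 6); diag(M) <- 0
  expect_identical(warpPath(matchTimepoints(M)), 1:6)
})

test_that("the path can never step backward in time", {
  # row 3's unconstrained minimum is column 2, but path(2) = 4
  M <- matrix(10, 6, 6)
  M[1, 1] <- 0
  M[2, 4] <- 0
  M[3, 2] <- 0; M[3, 5] <- 1
  M[4, ] <- c(9, 9, 9, 5, 6, 7)
  M[5, 6] <- 2
  M[6, 6] <- 0
  path <- warpPath(matchTimepoints(M))
  expect_identical(path[2], 4L)
  expect_true(path[3] %in% 4:6)
  expect_identical(path[3], 5L)
  expect_true(all(diff(path) >= 0))
})

test_that("greedy matching agrees with an independent oracle on 1000
           random matrices", {
  set.seed(404)
  for (i in seq_len(1000)) {
    M <- matrix(runif(36), 6, 6)
    expect_identical(warpPath(matchTimepoints(M)), greedyOracle(M))
  }
})

test_that("monotone row minima are matched exactly, and ties go early", {
  M <- matrix(5, 6, 6)
  mins <- c(1, 2, 2, 4, 5, 6)
  for (t in 1:6) M[t, mins[t]] <- 0
  expect_identical(warpPath(matchTimepoints(M)), as.integer(mins))
  tie <- matrix(1, 2, 6) # all equal: earliest admissible column wins
  expect_identical(warpPath(matchTimepoints(tie)), c(1L, 1L))
})

test_that("a +1 cohort temporal offset shifts the matched path", {
  spec <- syntheticSpec(nSpecies = 2, nNuclei = c(3000L, 3010L),
                        eggLength = c(400, 402), shiftField = c(0, 0),
                        temporalOffset = c(0L, 1L), seed = 12)
  prof <- enumerateCellTypes(list(
    binarize(generateAtlas(spec, 1)$atlas),
    binarize(generateAtlas(spec, 2)$atlas)))
  path <- warpPath(matchTimepoints(
    profileDistanceMatrix(prof[[1]], prof[[2]])))
  # the target lags one cohort: expect path(t) = t + 1 (clamped at 6)
  expected <- pmin(1:6 + 1L, 6L)
  expected[1] <- 1L # forced anchor
  expect_gte(sum(path == expected), 4)
  expect_true(all(diff(path) >= 0))
})

test_that("hourglass curve averages all unordered species pairs", {
  P <- lapply(1:5, function(s)
    mkProfile(matrix(0.1 * s, 2, 6), species = paste0("s", s),
              types = c("x", "y")))
  hc <- hourglassCurve(P)
  expect_equal(unique(hc$nPairs), 10L) # choose(5, 2)
  expect_identical(nrow(hc), 6L)
  # identical species: zero mean and SEM
  same <- lapply(1:3, function(s) P[[1]])
  hc0 <- hourglassCurve(same)
  expect_equal(hc0$mean, rep(0, 6))
  expect_equal(hc0$sem, rep(0, 6))
  # label permutation leaves the curve unchanged
  expect_equal(hourglassCurve(P[c(3, 1, 5, 2, 4)])$mean, hc$mean)
  expect_error(hourglassCurve(P[1]), ">= 2")
})

test_that("species built to converge have a strictly decreasing curve", {
  P <- lapply(1:4, function(s) {
    p <- vapply(1:6, function(t) 0.5 + 0.05 * s * (6 - t) / 5, 0)
    mkProfile(rbind(p, 1 - p), species = paste0("s", s),
              types = c("x", "y"))
  })
  hc <- hourglassCurve(P)
  expect_true(all(diff(hc$mean) < 0))
  expect_equal(hc$mean[6], 0)
})
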
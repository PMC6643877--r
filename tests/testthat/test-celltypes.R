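# Thresholding, binary calls, cell-type enumeration and gene-count
# dynamics.

test_that("threshold is mode plus sample standard deviation", {
  # exact-tie mode rule: mode 0.1, sd 0.2, threshold 0.3; only 0.5 is on
  vals <- c(0.1, 0.1, 0.1, 0.5)
  thr <- expressionThreshold(vals)
  expect_equal(thr, 0.3)
  expect_identical(vals > thr, c(FALSE, FALSE, FALSE, TRUE))
  expect_warning(t2 <- expressionThreshold(rep(2, 5)), "identical")
  expect_equal(t2, 2)
  expect_false(any(rep(2, 5) > t2)) # strict rule: all off
})

test_that("histogram-mode threshold separates a bimodal mixture", {
  set.seed(202)
  vals <- c(pmax(rnorm(4500, 0.1, 0.02), 0), rnorm(500, 0.8, 0.05))
  thr <- expressionThreshold(vals)
  high <- vals[4501:5000]
  expect_gte(mean(high > thr), 0.99)
  expect_gt(thr, 0.12) # above the background mode
})

test_that("binarize calls exactly a sharp expressed domain", {
  E <- lapply(1:6, function(t) {
    m <- matrix(0, 200, 2, dimnames = list(NULL, c("a", "b")))
    m[41:80, "a"] <- 1
    m[1:100, "b"] <- t / 6
    m
  })
  atl <- tinyAtlas(E)
  calls <- binarize(atl)
  expect_identical(which(callMatrix(calls, 3)[, "a"]), 41:80)
  expect_error(binarize(atl, genes = c("a", "zzz")), "zzz")
  # identical values across two cohorts give identical thresholds/calls
  expect_equal(thresholds(calls)["a", 1], thresholds(calls)["a", 2])
  expect_identical(callMatrix(calls, 1)[, "a"], callMatrix(calls, 2)[, "a"])
})

test_that("all-off nuclei form a single empty cell type of proportion 1", {
  calls <- new("BinaryCalls", species = "s", genes = c("a", "b"),
               calls = rep(list(matrix(FALSE, 50, 2,
                                       dimnames = list(NULL, c("a", "b")))),
                           6),
               thresholds = matrix(1, 2, 6))
  prof <- enumerateCellTypes(calls)[[1]]
  expect_identical(cellTypes(prof), "")
  expect_equal(unname(proportions(prof)), matrix(1, 1, 6))
})

test_that("the 0.1% filter is strict: 1/1000 stays, 1/1001 goes", {
  mk <- function(n) {
    cm <- matrix(FALSE, n, 2, dimnames = list(NULL, c("a", "b")))
    cm[1, 1] <- TRUE # the rare combination "a", exactly once
    new("BinaryCalls", species = paste0("s", n), genes = c("a", "b"),
        calls = list(cm), thresholds = matrix(1, 2, 1))
  }
  keep <- enumerateCellTypes(mk(1000))[[1]]
  expect_true("a" %in% cellTypes(keep))
  drop <- enumerateCellTypes(mk(1001))[[1]]
  expect_false("a" %in% cellTypes(drop))
  # filtered mass is not renormalised away from the remaining types
  expect_equal(colSums(proportions(drop)), 1000 / 1001,
               ignore_attr = TRUE)
})

test_that("raising min_frac never increases the observed-type count", {
  calls <- binarize(smallGen()$atlas)
  nTypes <- vapply(c(0, 0.0005, 0.001, 0.005, 0.02), function(f)
    length(cellTypes(enumerateCellTypes(calls, minFrac = f)[[1]])), 1L)
  expect_true(all(diff(nTypes) <= 0))
})

test_that("unfiltered proportions partition every nucleus exactly once", {
  calls <- binarize(smallGen()$atlas)
  prof <- enumerateCellTypes(calls, minFrac = 0)[[1]]
  expect_equal(unname(colSums(proportions(prof))), rep(1, 6))
  # observed types are subsets of the 2^9 possibilities
  expect_lte(length(cellTypes(prof)), 512)
})

test_that("cell-type summary reproduces the combinatorics table shape", {
  calls <- binarize(smallGen()$atlas)
  prof <- enumerateCellTypes(calls)
  summ <- cellTypeSummary(prof)
  expect_identical(summ$possible, choose(9, summ$size))
  expect_true(all(summ$observed <= summ$possible))
})

test_that("gene-count distributions are per-cohort proportions", {
  calls <- binarize(smallGen()$atlas)
  gcd <- geneCountDistribution(calls)
  expect_equal(unname(colSums(gcd)), rep(1, 6))
  # disjoint stripes never co-fire
  E <- lapply(1:6, function(t) {
    m <- matrix(0, 300, 2, dimnames = list(NULL, c("eve", "odd")))
    m[seq(1, 300, by = 4), "eve"] <- 1
    m[seq(3, 300, by = 4), "odd"] <- 1
    m
  })
  disj <- binarize(tinyAtlas(E))
  expect_equal(unname(geneCountDistribution(disj)["2", ]), rep(0, 6))
})

test_that("shrinking stripe overlap yields strictly decreasing
           co-expression", {
  stripes <- function(offset) list(
    centers = seq(0.3, 0.7, length.out = 5) + offset,
    sigma = 0.02, amp = 1)
  spec <- syntheticSpec(
    nSpecies = 1, nNuclei = 2500L, eggLength = 400,
    genes = c("p1", "p2"), geneRoles = c("pairrule", "pairrule"),
    domains = list(p1 = stripes(0), p2 = stripes(0.05)),
    shiftField = 0, temporalOffset = 0L,
    widthFactor = c(1.8, 1.5, 1.25, 1.05, 0.9, 0.8),
    furrows = list(), seed = 61)
  calls <- binarize(generateAtlas(spec, 1)$atlas)
  both <- geneCountDistribution(calls)["2", ]
  expect_true(all(diff(both) < 0))
  expect_gt(both[1], 0)
})
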
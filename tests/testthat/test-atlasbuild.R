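# Gain/offset estimation, embryo averaging, and the quality metric.

makeEmbryo <- function(expr, species = "x") {
  n <- nrow(expr)
  Pointcloud(coords = cbind(seq_len(n), (seq_len(n) %% 7), 0.1 * seq_len(n)),
             expr = expr, species = species, stage = 0)
}

test_that("identical embryos give unit gains, zero offsets and S = 0", {
  e <- makeEmbryo(cbind(g = c(0, 1, 2, 5, 0.5, 3)))
  go <- estimateGainOffset(list(e, e))
  expect_equal(go$gain, c(1, 1))
  expect_equal(go$offset, c(0, 0), tolerance = 1e-12)
  sl <- averageEmbryos(list(e, e), go)
  expect_equal(unname(sl$S[, "g"]), rep(0, 6))
  expect_equal(unname(sl$E[, "g"]), c(0, 1, 2, 5, 0.5, 3))
})

test_that("an exact affine pair is mapped onto the consensus", {
  v <- c(0, 1, 2, 5, 0.5, 3, 4, 2.5)
  e1 <- makeEmbryo(cbind(g = v))
  e2 <- makeEmbryo(cbind(g = 2 * v + 5))
  go <- estimateGainOffset(list(e1, e2))
  expect_equal(mean(go$gain), 1) # scale convention
  V <- cbind(v, 2 * v + 5)
  Vc <- sweep(sweep(V, 2, go$offset), 2, go$gain, "/")
  expect_equal(Vc[, 1], Vc[, 2], tolerance = 1e-8, ignore_attr = TRUE)
  # residual across-embryo variance vanishes for an exact affine family
  expect_lt(sum(apply(Vc, 1, var)), 1e-14)
})

test_that("recorded synthetic gains are recovered within 5% at 1% noise", {
  spec <- syntheticSpec(nSpecies = 1, nNuclei = 2000L, eggLength = 400,
                        noise = list(gainSdLog = 0.2,
                                     offsetRange = c(0.01, 0.05),
                                     nucleusSd = 0.01), seed = 9)
  es <- generateEmbryoSet(spec, 8L, 6L, 1L)
  go <- estimateGainOffset(es$embryos)
  trueGain <- es$gains / mean(es$gains) # same mean-gain-1 convention
  for (d in split(go, go$gene)) {
    d <- d[order(d$embryo), ]
    expect_lt(max(abs(d$gain / trueGain - 1)), 0.05)
  }
})

test_that("correction never increases total across-embryo variance", {
  spec <- syntheticSpec(nSpecies = 1, nNuclei = 900L, eggLength = 400,
                        seed = 27)
  es <- generateEmbryoSet(spec, 5L, 5L, 1L)
  go <- estimateGainOffset(es$embryos)
  for (g in c("hb", "eve", "tll")) {
    V <- sapply(es$embryos, function(e) exprValues(e)[, g])
    cr <- go[go$gene == g, ]
    cr <- cr[order(cr$embryo), ]
    Vc <- sweep(sweep(V, 2, cr$offset), 2, cr$gain, "/")
    expect_lte(sum(apply(Vc, 1, var)), sum(apply(V, 1, var)))
  }
})

test_that("constant-expression embryos fall back to gain 1 with a warning", {
  e1 <- makeEmbryo(cbind(g = c(1, 2, 3, 4)))
  e2 <- makeEmbryo(cbind(g = rep(2, 4)))
  expect_warning(go <- estimateGainOffset(list(e1, e2)), "constant")
  expect_equal(go$gain[2], 1)
})

test_that("averaging recovers generative means within the CLT bound", {
  spec <- syntheticSpec(nSpecies = 1, nNuclei = 1500L, eggLength = 400,
                        noise = list(gainSdLog = 0, offsetRange = c(0, 0),
                                     nucleusSd = 0.05), seed = 16)
  gen <- generateAtlas(spec, 1)
  es <- generateEmbryoSet(spec, 8L, 6L, 1L, atlas = gen)
  sl <- averageEmbryos(es$embryos, NULL)
  for (g in c("hb", "eve")) {
    truth <- exprValues(gen$atlas, 6)[, g]
    sigma <- 0.05 * max(truth)
    # away from zero the clipping at 0 plays no role and the CLT applies:
    # mean of 8 embryos has sd sigma/sqrt(8), 95% within 1.96 sd
    sel <- truth > 3 * sigma
    err <- abs(sl$E[sel, g] - truth[sel])
    expect_gt(mean(err <= 1.96 * sigma / sqrt(8)), 0.9)
    expect_equal(mean(sl$S[sel, g]), sigma, tolerance = 0.1)
  }
})

test_that("single-embryo cohorts report S as missing", {
  e <- makeEmbryo(cbind(g = c(1, 2, 3)))
  sl <- averageEmbryos(list(e))
  expect_true(all(is.na(sl$S)))
  expect_equal(unname(sl$E[, 1]), c(1, 2, 3))
})

test_that("a rebuilt atlas carries the quality metric per gene", {
  spec <- syntheticSpec(nSpecies = 1, nNuclei = 700L, eggLength = 380,
                        noise = list(gainSdLog = 0.1,
                                     offsetRange = c(0.01, 0.03),
                                     nucleusSd = 0.02), seed = 31)
  gen <- generateAtlas(spec, 1)
  sets <- lapply(1:6, function(t)
    generateEmbryoSet(spec, 3L, t, 1L, atlas = gen)$embryos)
  atl <- buildAtlas(sets)
  expect_true(validObject(atl))
  q <- expressionQuality(atl)
  expect_identical(names(q$perGene), genes(atl))
  expect_true(all(q$perGene > 0))
  # constant std tensor: quality equals the constant
  atl@S <- lapply(atl@S, function(m) m * 0 + 0.3)
  q2 <- expressionQuality(atl)
  expect_equal(unname(q2$perGene), rep(0.3, length(genes(atl))))
})

test_that("embryos with mismatched indexing are rejected", {
  e1 <- makeEmbryo(cbind(g = c(1, 2, 3)))
  e2 <- makeEmbryo(cbind(g = c(1, 2, 3, 4)))
  expect_error(estimateGainOffset(list(e1, e2)), "indexing")
  expect_error(estimateGainOffset(list(e1)), ">= 2")
})
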
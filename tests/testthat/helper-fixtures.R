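# Shared fixtures, generated once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small single-species generated atlas (uniform density, mel-like)
smallGen <- function() fixture("smallGen", function() {
  generateAtlas(syntheticSpec(nSpecies = 1, nNuclei = 1500L,
                              eggLength = 400, seed = 101), 1)
})

# 6000-nucleus sphere, uniform density (geometry oracles)
sphereGen <- function() fixture("sphereGen", function() {
  generateAtlas(syntheticSpec(nSpecies = 1, nNuclei = 6000L,
                              eggLength = 200, maxRadius = 100,
                              furrows = list(), seed = 42), 1)
})

# pair of same-morphology species differing by a 2% EL expression shift
shiftPairGen <- function() fixture("shiftPairGen", function() {
  spec <- syntheticSpec(nSpecies = 2, nNuclei = c(6000L, 6000L),
                        eggLength = c(400, 400),
                        shiftField = c(0, 0.02),
                        temporalOffset = c(0L, 0L), seed = 5)
  list(spec = spec,
       ref = generateAtlas(spec, 1),
       target = generateAtlas(spec, 2))
})

# hand-built 4-nucleus planar pointcloud with two triangles
toyPointcloud <- function() {
  coords <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 1))
  expr <- cbind(gA = c(0, 1, 2, 3), gB = c(4, 3, 2, 1))
  nb <- list(c(2L, 3L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(2L, 3L))
  Pointcloud(coords = coords, expr = expr, neighbors = nb,
             species = "toy", stage = 10,
             metadata = list(dorsal = c(0, 0, 1)))
}

# tiny Atlas built directly from matrices (2 genes, constant nuclei)
tinyAtlas <- function(E6, positions = NULL, species = "tiny",
                      eggLength = 100) {
  n <- nrow(E6[[1]])
  if (is.null(positions))
    positions <- rep(list(cbind(seq_len(n) * 10, 0, seq_len(n))), 6L)
  new("Atlas", species = species, genes = colnames(E6[[1]]),
      positions = positions, E = E6, S = list(),
      correspondence = rep(list(seq_len(n)), 5L), eggLength = eggLength,
      metadata = list(dorsal = c(0, 0, 1)))
}

# rigid rotation matrix about an arbitrary fixed axis
rot3 <- function(angle = 0.7, axis = c(1, 2, 3)) {
  u <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
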
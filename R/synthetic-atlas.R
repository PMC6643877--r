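## Synthetic multi-species blastoderm atlases with recorded ground truth.
##
## Nuclei are placed on an ellipsoid-of-revolution surface on latitude
## rings spaced along the meridian arc, with jittered angular positions
## whose local spacing follows an inverse-CDF of the target density field
## (furrow depressions -> locally sparser nuclei). The surface mesh is a
## deterministic ring-zipper triangulation plus fans at the two poles; it
## is closed and manifold by construction. Expression is a function of AP
## position: products of logistic boundary functions for gap/terminal-like
## genes and sums of 7 Gaussian stripes for pair-rule-like genes, sharpened
## per cohort and shifted along AP per species.

## evaluate a block with a temporary RNG seed, restoring global RNG state
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## derived 31-bit sub-seeds; the geometry seed depends only on the seed and
## the species' morphological parameters, so two species with identical
## morphology share identical nucleus placements (and zero shift + zero
## noise then gives identical atlases).
.geomSeed <- function(spec, s) {
  v <- (as.double(spec@seed) * 10007 + spec@nNuclei[s] * 13 +
          round(spec@eggLength[s] * 10) + round(spec@maxRadius[s] * 7))
  as.integer(v %% 2147483647)
}

.noiseSeed <- function(spec, s, cohort, tag) {
  v <- (as.double(spec@seed) * 7919 + s * 104729 + cohort * 1299709 + tag)
  as.integer(v %% 2147483647)
}

## surface area of an ellipsoid of revolution, semi-axes (a, b, b)
.ellipsoidArea <- function(a, b) {
  if (abs(a - b) < 1e-9 * max(a, b)) return(4 * pi * a^2)
  if (a > b) { # prolate
    e <- sqrt(1 - (b / a)^2)
    2 * pi * b^2 * (1 + (a / (b * e)) * asin(e))
  } else {     # oblate
    e <- sqrt(1 - (a / b)^2)
    2 * pi * b^2 * (1 + ((1 - e^2) / e) * atanh(e))
  }
}

## wrapped angular difference in [-pi, pi)
.wrapAngle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y
}

## target relative density field in (ap, phi); clamped away from zero
.densityField <- function(spec, ap, phi) {
  d <- rep(1, length(ap))
  for (f in spec@furrows) {
    g <- exp(-0.5 * ((ap - f$ap) / f$sigmaAp)^2)
    if (!is.na(f$phi) && !is.na(f$sigmaPhi))
      g <- g * exp(-0.5 * (.wrapAngle(phi - f$phi) / f$sigmaPhi)^2)
    d <- d - f$depth * g
  }
  pmax(d, 0.15)
}

## AP expression pattern of one gene at one effective cohort (no noise)
.genePattern <- function(spec, gene, ap, effCohort, shift = 0) {
  g <- match(gene, spec@genes)
  if (is.na(g)) stop("unknown gene: ", gene)
  role <- spec@geneRoles[g]
  wf <- spec@widthFactor[effCohort]
  af <- spec@ampFactor[[role]][effCohort]
  x <- ap - shift
  d <- spec@domains[[g]]
  if (role == "pairrule") {
    sig <- d$sigma * wf
    val <- rowSums(vapply(d$centers, function(cc)
      exp(-0.5 * ((x - cc) / sig)^2), numeric(length(x))))
    return(pmax(d$amp * af * val, 0))
  }
  val <- numeric(length(x))
  for (dom in d) {
    w <- dom$width * wf
    left <- if (dom$lo <= 0) 1 else stats::plogis((x - dom$lo) / w)
    right <- if (dom$hi >= 1) 1 else stats::plogis((dom$hi - x) / w)
    val <- val + dom$amp * left * right
  }
  pmax(af * val, 0)
}

## effective dynamics cohort after the species' temporal offset, clamped
.effCohort <- function(spec, s, cohort) {
  pmin(pmax(cohort - spec@temporalOffset[s], 1L), 6L)
}

## ---- geometry ------------------------------------------------------------

## zipper-triangulate the annulus between two rings given angular positions
## (phiA, phiB) and global indices (idxA, idxB); returns a (nA+nB) x 3
## integer matrix of triangles
.zipperRings <- function(phiA, phiB, idxA, idxB) {
  oa <- order(phiA); phiA <- phiA[oa]; idxA <- idxA[oa]
  ob <- order(phiB); phiB <- phiB[ob]; idxB <- idxB[ob]
  nA <- length(phiA); nB <- length(phiB)
  # rotate ring B to start at its vertex angularly closest to phiA[1]
  j0 <- which.min(abs(.wrapAngle(phiB - phiA[1])))
  rot <- c(seq(j0, nB), if (j0 > 1) seq_len(j0 - 1))
  phiB <- phiB[rot]; idxB <- idxB[rot]
  # unwrapped, monotone angle sequences with a closing sentinel
  ua <- c(phiA, phiA[1] + 2 * pi)
  ub <- phiB
  if (nB > 1) ub[-1] <- phiB[1] + cumsum((diff(phiB) + 2 * pi) %% (2 * pi))
  ub <- ub - 2 * pi * round((ub[1] - ua[1]) / (2 * pi))
  ub <- c(ub, ub[1] + 2 * pi)
  tris <- matrix(0L, nA + nB, 3)
  ia <- 1L; jb <- 1L; t <- 0L
  wrapA <- function(i) ((i - 1L) %% nA) + 1L
  wrapB <- function(j) ((j - 1L) %% nB) + 1L
  while (ia <= nA || jb <= nB) {
    advanceA <- if (ia > nA) FALSE
      else if (jb > nB) TRUE
      else ua[ia + 1L] <= ub[jb + 1L]
    t <- t + 1L
    if (advanceA) {
      tris[t, ] <- c(idxA[ia], idxB[wrapB(jb)], idxA[wrapA(ia + 1L)])
      ia <- ia + 1L
    } else {
      tris[t, ] <- c(idxA[wrapA(ia)], idxB[jb], idxB[wrapB(jb + 1L)])
      jb <- jb + 1L
    }
  }
  tris[seq_len(t), , drop = FALSE]
}

## place ~n nuclei on the ellipsoid surface; returns coords, mesh triangles,
## true (ap, phi) and the meridian arc spacing used
.placeNuclei <- function(spec, s) {
  a <- spec@eggLength[s] / 2
  b <- spec@maxRadius[s]
  n <- spec@nNuclei[s]
  A <- .ellipsoidArea(a, b)
  s0 <- sqrt(2 * A / (sqrt(3) * n)) # hexagonal-packing spacing
  if (s0 < 2.5)
    stop(sprintf(
      "infeasible nucleus count: %d nuclei on %.0f um^2 implies %.2f um spacing",
      n, A, s0))
  # meridian arc length, theta in [0, pi], x = -a cos(theta)
  th <- seq(0, pi, length.out = 4001)
  ds <- sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2)
  arc <- c(0, cumsum((ds[-1] + ds[-length(ds)]) / 2 * diff(th)))
  Lm <- arc[length(arc)]
  dRing <- s0 * sqrt(3) / 2
  nRings <- max(3L, round(Lm / dRing) - 1L)
  ringArc <- seq_len(nRings) * Lm / (nRings + 1)
  ringTh <- stats::approx(arc, th, xout = ringArc)$y
  ringR <- b * sin(ringTh)
  ringAp <- (-a * cos(ringTh) + a) / (2 * a)
  # per-ring counts proportional to circumference x mean density
  phiGrid <- seq(-pi, pi, length.out = 361)[-361]
  meanDens <- vapply(seq_len(nRings), function(i)
    mean(.densityField(spec, rep(ringAp[i], length(phiGrid)), phiGrid)), 0)
  w <- ringR * meanDens
  counts <- pmax(3L, round(w / sum(w) * (n - 2L)))
  # deterministic count adjustment toward the target
  delta <- (n - 2L) - sum(counts)
  ord <- order(w, decreasing = TRUE)
  i <- 1L
  while (delta != 0L) {
    k <- ord[((i - 1L) %% nRings) + 1L]
    if (delta > 0L) { counts[k] <- counts[k] + 1L; delta <- delta - 1L }
    else if (counts[k] > 3L) { counts[k] <- counts[k] - 1L; delta <- delta + 1L }
    i <- i + 1L
    if (i > 10L * nRings) break
  }
  coordList <- vector("list", nRings)
  phiList <- vector("list", nRings)
  apList <- vector("list", nRings)
  arcJitterSd <- 0.06 * dRing
  for (i in seq_len(nRings)) {
    ni <- counts[i]
    dens <- .densityField(spec, rep(ringAp[i], length(phiGrid)), phiGrid)
    cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
    u0 <- stats::runif(1)
    q <- ((seq_len(ni) - 0.5 + stats::rnorm(ni, 0, 0.08)) / ni + u0) %% 1
    phi <- stats::approx(c(0, cdf), c(phiGrid, pi), xout = q,
                         ties = "ordered")$y
    arcI <- ringArc[i] + stats::rnorm(ni, 0, arcJitterSd)
    arcI <- pmin(pmax(arcI, 1e-6), Lm - 1e-6)
    thI <- stats::approx(arc, th, xout = arcI)$y
    x <- -a * cos(thI)
    r <- b * sin(thI)
    # phi = 0 dorsal (+z), +pi/2 left (+y), +/-pi ventral (-z)
    coordList[[i]] <- cbind(x = x, y = r * sin(phi), z = r * cos(phi))
    phiList[[i]] <- phi
    apList[[i]] <- (x + a) / (2 * a)
  }
  coordsRings <- do.call(rbind, coordList)
  nTot <- nrow(coordsRings) + 2L
  coords <- rbind(c(-a, 0, 0), coordsRings, c(a, 0, 0))
  apAll <- c(0, unlist(apList), 1)
  phiAll <- c(0, unlist(phiList), 0)
  ringIdx <- split(seq_len(nrow(coordsRings)) + 1L,
                   rep.int(seq_len(nRings), counts))
  # mesh: pole fans + zipper strips between consecutive rings
  tris <- list()
  r1 <- ringIdx[[1]]
  o1 <- order(phiList[[1]])
  f <- r1[o1]
  tris[[1]] <- cbind(1L, f, f[c(seq_along(f)[-1], 1L)])
  for (i in seq_len(nRings - 1L))
    tris[[i + 1L]] <- .zipperRings(phiList[[i]], phiList[[i + 1L]],
                                   ringIdx[[i]], ringIdx[[i + 1L]])
  rN <- ringIdx[[nRings]]
  oN <- order(phiList[[nRings]])
  fN <- rN[oN]
  tris[[nRings + 1L]] <- cbind(nTot, fN, fN[c(seq_along(fN)[-1], 1L)])
  triangles <- do.call(rbind, tris)
  list(coords = coords, triangles = triangles, ap = apAll, phi = phiAll,
       spacing = s0, area = A, nRings = nRings)
}

## triangle list -> symmetric neighbor lists
.trianglesToNeighbors <- function(triangles, n) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)],
             triangles[, c(1, 3)])
  nb <- rep(list(integer(0)), n)
  sp <- split(c(e[, 2], e[, 1]),
              factor(c(e[, 1], e[, 2]), levels = seq_len(n)))
  unname(lapply(sp, function(v) sort(unique(as.integer(v)))))
}

## ---- generators ----------------------------------------------------------

#' Generate a synthetic species atlas with ground truth
#'
#' Builds one species' atlas under a [SyntheticSpec]: nuclei on an
#' ellipsoid-of-revolution surface with furrow density depressions, mean
#' expression of every panel gene at all six cohorts (patterns shifted along
#' AP by the species' shift and sharpened per cohort), identity cross-cohort
#' correspondence, and a ground-truth record of everything a recovery test
#' needs. Output is deterministic given `(spec, speciesIndex)`.
#'
#' @param spec a [SyntheticSpec].
#' @param speciesIndex which species to generate (1-based).
#' @return list with elements `atlas` (an [Atlas]) and `truth` (list:
#'   `shift`, `temporalOffset`, `domains`, `furrows`, `ap`, `phi`,
#'   `spacing`, `surfaceArea`, `triangles`).
#' @examples
#' spec <- syntheticSpec(nSpecies = 1, nNuclei = 600L, seed = 3)
#' atl <- generateAtlas(spec, 1)$atlas
#' atl
#' @export
generateAtlas <- function(spec, speciesIndex = 1L) {
  stopifnot(is(spec, "SyntheticSpec"),
            speciesIndex >= 1L, speciesIndex <= length(spec@speciesNames))
  s <- as.integer(speciesIndex)
  geo <- .withSeed(.geomSeed(spec, s), .placeNuclei(spec, s))
  n <- nrow(geo$coords)
  ng <- length(spec@genes)
  E <- vector("list", 6L)
  for (t in 1:6) {
    effT <- .effCohort(spec, s, t)
    m <- matrix(0, n, ng, dimnames = list(NULL, spec@genes))
    for (g in spec@genes)
      m[, g] <- .genePattern(spec, g, geo$ap, effT,
                             shift = spec@shiftField[s])
    E[[t]] <- m
  }
  atlas <- new("Atlas",
    species = spec@speciesNames[s], genes = spec@genes,
    positions = rep(list(geo$coords), 6L), E = E, S = list(),
    correspondence = rep(list(seq_len(n)), 5L),
    eggLength = spec@eggLength[s],
    metadata = list(dorsal = c(0, 0, 1), anterior = c(-1, 0, 0),
                    synthetic = TRUE))
  truth <- list(shift = spec@shiftField[s],
                temporalOffset = spec@temporalOffset[s],
                domains = spec@domains, furrows = spec@furrows,
                ap = geo$ap, phi = geo$phi, spacing = geo$spacing,
                surfaceArea = geo$area, triangles = geo$triangles)
  list(atlas = atlas, truth = truth)
}

#' Noise-free Pointcloud view of a generated atlas cohort
#'
#' Converts one cohort of a [generateAtlas()] result into a [Pointcloud]
#' carrying the generator's surface mesh as its neighbor relation and the
#' atlas means as expression: the idealised embryo morphology/expression
#' object used by the morphology operations.
#'
#' @param gen result of [generateAtlas()].
#' @param cohort time cohort 1..6 (default 6).
#' @return a [Pointcloud].
#' @export
atlasPointcloud <- function(gen, cohort = 6L) {
  atl <- gen$atlas
  stopifnot(is(atl, "Atlas"), cohort >= 1L, cohort <= 6L)
  Pointcloud(
    coords = atl@positions[[cohort]], expr = atl@E[[cohort]],
    neighbors = .trianglesToNeighbors(gen$truth$triangles,
                                      nrow(atl@positions[[cohort]])),
    species = atl@species, stage = .stageForCohort(cohort),
    metadata = atl@metadata)
}

#' Generate a set of noisy synthetic embryos for one cohort
#'
#' Each embryo shares the parent atlas's nucleus indexing; its expression is
#' `gain_e * atlasMean + offset_e + noise`, clipped at zero, with the
#' per-embryo gain lognormal, the offset a positive uniform background, and
#' per-nucleus Gaussian noise with sd equal to `noise$nucleusSd` times each
#' gene's maximum mean level. True gains and offsets are returned.
#'
#' @param spec a [SyntheticSpec].
#' @param nEmbryos number of embryos (>= 1).
#' @param cohort time cohort 1..6.
#' @param speciesIndex species to emulate.
#' @param atlas optional pre-generated result of [generateAtlas()] for this
#'   species (regenerated when NULL).
#' @return list with `embryos` (list of [Pointcloud]), `gains`, `offsets`
#'   (numeric per embryo), and `atlas` (the parent atlas result).
#' @export
generateEmbryoSet <- function(spec, nEmbryos, cohort, speciesIndex = 1L,
                              atlas = NULL) {
  stopifnot(nEmbryos >= 1L, cohort >= 1L, cohort <= 6L)
  if (is.null(atlas)) atlas <- generateAtlas(spec, speciesIndex)
  atl <- atlas$atlas
  E <- atl@E[[cohort]]
  geoNb <- .trianglesToNeighbors(atlas$truth$triangles, nrow(E))
  maxPerGene <- apply(E, 2, max)
  sdPerGene <- spec@noise$nucleusSd * maxPerGene
  .withSeed(.noiseSeed(spec, speciesIndex, cohort, nEmbryos), {
    gains <- exp(stats::rnorm(nEmbryos, 0, spec@noise$gainSdLog))
    offsets <- stats::runif(nEmbryos, spec@noise$offsetRange[1],
                            spec@noise$offsetRange[2])
    embryos <- vector("list", nEmbryos)
    for (e in seq_len(nEmbryos)) {
      noise <- sweep(matrix(stats::rnorm(length(E)), nrow(E), ncol(E)),
                     2, sdPerGene, "*")
      v <- pmax(gains[e] * E + offsets[e] + noise, 0)
      colnames(v) <- atl@genes
      embryos[[e]] <- Pointcloud(
        coords = atl@positions[[cohort]], expr = v, neighbors = geoNb,
        species = atl@species, stage = .stageForCohort(cohort),
        metadata = list(dorsal = c(0, 0, 1), anterior = c(-1, 0, 0),
                        embryo = e, synthetic = TRUE))
    }
    list(embryos = embryos, gains = gains, offsets = offsets, atlas = atlas)
  })
}
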
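## Atlas construction from pre-registered pointclouds sharing a nucleus
## indexing: per-embryo affine gain/offset normalisation (least squares
## against an iteratively refined consensus), closest-nucleus averaging,
## and the per-gene inter-embryo standard-deviation quality metric.

#' Estimate per-embryo gains and offsets
#'
#' Fits, for each gene, an affine model `raw_e = gain_e * consensus +
#' offset_e` per embryo, where the consensus is the per-nucleus mean of the
#' corrected embryos. The fit alternates (a) consensus update and (b)
#' per-embryo ordinary least squares, for at most `maxIter` iterations or
#' until the relative parameter change falls below `tol`. The scale
#' indeterminacy is fixed by constraining the mean gain to 1. Applying the
#' inverse transforms `(raw - offset)/gain` minimises the total
#' across-embryo variance among per-embryo affine corrections.
#'
#' A constant-expression embryo leaves its gain undefined: it is reported
#' as gain 1 with the mean difference as offset, with a warning. Negative
#' fitted gains (a failed embryo) are clamped to 1 with a warning.
#'
#' @param embryos list of >= 2 `Pointcloud`s sharing nucleus indexing.
#' @param gene gene name(s); default all shared genes.
#' @param maxIter,tol iteration controls.
#' @return data.frame with columns `embryo`, `gene`, `gain`, `offset`.
#' @export
estimateGainOffset <- function(embryos, gene = NULL, maxIter = 5L,
                               tol = 1e-8) {
  stopifnot(length(embryos) >= 2L)
  ns <- vapply(embryos, nNuclei, 1L)
  if (length(unique(ns)) != 1L)
    stop("embryos must share nucleus indexing (equal nucleus counts)")
  if (is.null(gene)) gene <- Reduce(intersect, lapply(embryos, genes))
  out <- vector("list", length(gene))
  for (gi in seq_along(gene)) {
    g <- gene[gi]
    V <- vapply(embryos, function(e) {
      if (!g %in% genes(e)) stop("gene not present in all embryos: ", g)
      e@expr[, g]
    }, numeric(ns[1])) # nuclei x embryos
    nE <- ncol(V)
    gain <- rep(1, nE); offset <- rep(0, nE)
    constant <- apply(V, 2, stats::var) < .Machine$double.eps
    if (any(constant))
      warning("constant-expression embryo(s) for gene ", g,
              ": gain fixed at 1")
    for (it in seq_len(maxIter)) {
      corrected <- sweep(sweep(V, 2, offset), 2, gain, "/")
      M <- rowMeans(corrected)
      vM <- stats::var(M)
      gainNew <- gain; offsetNew <- offset
      for (e in seq_len(nE)) {
        if (constant[e] || vM < .Machine$double.eps) {
          gainNew[e] <- 1
          offsetNew[e] <- mean(V[, e]) - mean(M)
          next
        }
        b <- stats::cov(M, V[, e]) / vM
        if (b <= 0) {
          warning("non-positive fitted gain for embryo ", e, ", gene ", g,
                  "; clamped to 1")
          b <- 1
        }
        gainNew[e] <- b
        offsetNew[e] <- mean(V[, e]) - b * mean(M)
      }
      # mean-gain-1 constraint over the fitted embryos; constant-expression
      # embryos keep their conventional gain of 1
      if (any(!constant)) {
        gbar <- mean(gainNew[!constant])
        gainNew[!constant] <- gainNew[!constant] / gbar
      }
      delta <- max(abs(gainNew - gain), abs(offsetNew - offset))
      gain <- gainNew; offset <- offsetNew
      if (delta < tol * max(1, max(abs(gain)))) break
    }
    out[[gi]] <- data.frame(embryo = seq_len(nE), gene = g,
                            gain = gain, offset = offset)
  }
  do.call(rbind, out)
}

#' Average corrected embryos into an atlas cohort slice
#'
#' Applies the inverse gain/offset transform `(raw - offset)/gain` to each
#' embryo and computes, per nucleus and gene, the mean `E` and the sample
#' (n-1) standard deviation `S` across embryos. With a single embryo `S`
#' is reported as missing (NA).
#'
#' @param embryos list of `Pointcloud`s sharing nucleus indexing.
#' @param corrections data.frame from [estimateGainOffset()] (identity
#'   corrections when NULL).
#' @return list with matrices `E` (means) and `S` (sds; NA if n = 1), and
#'   `n` (number of embryos).
#' @export
averageEmbryos <- function(embryos, corrections = NULL) {
  stopifnot(length(embryos) >= 1L)
  gset <- Reduce(intersect, lapply(embryos, genes))
  n <- nNuclei(embryos[[1]])
  nE <- length(embryos)
  E <- matrix(0, n, length(gset), dimnames = list(NULL, gset))
  S <- matrix(NA_real_, n, length(gset), dimnames = list(NULL, gset))
  for (g in gset) {
    V <- vapply(embryos, function(e) e@expr[, g], numeric(n))
    V <- matrix(V, nrow = n)
    if (!is.null(corrections)) {
      cr <- corrections[corrections$gene == g, , drop = FALSE]
      if (nrow(cr) != nE)
        stop("corrections must cover every embryo for gene ", g)
      cr <- cr[order(cr$embryo), ]
      V <- sweep(sweep(V, 2, cr$offset), 2, cr$gain, "/")
    }
    E[, g] <- rowMeans(V)
    if (nE > 1L) S[, g] <- apply(V, 1, stats::sd)
  }
  list(E = E, S = S, n = nE)
}

#' Build a full Atlas from per-cohort embryo sets
#'
#' Runs [estimateGainOffset()] and [averageEmbryos()] for each cohort and
#' assembles an [Atlas] with the mean and std tensors. All embryos must
#' share one nucleus indexing (the synthetic setting), so positions are
#' taken from the first embryo of each cohort and cross-cohort
#' correspondence is the identity.
#'
#' @param embryoSets list of 6 lists of `Pointcloud`s (one per cohort).
#' @param species species label (default: from the first embryo).
#' @param normalize apply gain/offset correction (default TRUE).
#' @return an [Atlas] with `S` filled (NA slices for single-embryo cohorts).
#' @export
buildAtlas <- function(embryoSets, species = NULL, normalize = TRUE) {
  stopifnot(length(embryoSets) == 6L)
  first <- embryoSets[[1]][[1]]
  if (is.null(species)) species <- first@species
  positions <- vector("list", 6L); E <- vector("list", 6L)
  S <- vector("list", 6L)
  for (t in 1:6) {
    set <- embryoSets[[t]]
    if (!length(set)) stop("cohort ", t, " has no embryos")
    corr <- if (normalize && length(set) >= 2L)
      estimateGainOffset(set) else NULL
    slice <- averageEmbryos(set, corr)
    positions[[t]] <- coords(set[[1]])
    E[[t]] <- pmax(slice$E, 0)
    S[[t]] <- slice$S
  }
  md <- first@metadata[intersect(names(first@metadata),
                                 c("dorsal", "anterior"))]
  n <- vapply(positions, nrow, 1L)
  corrMaps <- lapply(1:5, function(t) {
    if (n[t] == n[t + 1]) seq_len(n[t]) else rep(NA_integer_, n[t])
  })
  eggL <- eggLength(first)
  new("Atlas", species = species, genes = colnames(E[[1]]),
      positions = positions, E = E, S = S, correspondence = corrMaps,
      eggLength = eggL, metadata = md)
}

#' Inter-embryo expression variability (atlas quality)
#'
#' The average standard deviation of expression values between the embryos
#' averaged into the atlas: mean of the std tensor over nuclei per
#' (gene, cohort), then over cohorts per gene. Lower is better.
#'
#' @param atlas an [Atlas] with its std tensor `S` available.
#' @return list with `byCohort` (gene x cohort matrix) and `perGene`
#'   (named numeric, mean across cohorts).
#' @export
expressionQuality <- function(atlas) {
  stopifnot(is(atlas, "Atlas"))
  if (!length(atlas@S)) stop("atlas has no std tensor S")
  byCohort <- vapply(atlas@S, function(m) colMeans(m),
                     numeric(length(atlas@genes)))
  dimnames(byCohort) <- list(atlas@genes, seq_len(ncol(byCohort)))
  list(byCohort = byCohort, perGene = rowMeans(byCohort))
}
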
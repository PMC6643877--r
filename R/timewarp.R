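## Developmental time matching between species via distances between
## cell-type proportion vectors, and the hourglass divergence curve.

## align two profiles over the union of their observed cell types
.alignedProportions <- function(ref, target) {
  if (!identical(ref@universe, target@universe))
    stop("profiles use different gene universes")
  types <- union(ref@types, target@types)
  pad <- function(p, have) {
    P <- matrix(0, length(types), ncol(have),
                dimnames = list(types, colnames(have)))
    P[match(p, types), ] <- have # match(): "" is a valid type label
    P
  }
  list(ref = pad(ref@types, ref@proportions),
       target = pad(target@types, target@proportions))
}

#' Distance matrix between cell-type profiles of two species
#'
#' Entry (a, b) is the Euclidean (not squared) distance between the
#' reference species' cohort-a proportion vector and the target species'
#' cohort-b vector, after aligning both profiles over the union of their
#' cell types (absent types count as 0).
#'
#' @param ref,target [CellTypeProfile] objects over the same gene universe.
#' @return numeric matrix, reference cohorts x target cohorts.
#' @export
profileDistanceMatrix <- function(ref, target) {
  stopifnot(is(ref, "CellTypeProfile"), is(target, "CellTypeProfile"))
  al <- .alignedProportions(ref, target)
  na <- ncol(al$ref); nb <- ncol(al$target)
  out <- matrix(NA_real_, na, nb)
  for (a in seq_len(na)) for (b in seq_len(nb))
    out[a, b] <- sqrt(sum((al$ref[, a] - al$target[, b])^2))
  out
}

#' Greedy monotone time-point matching
#'
#' Matches reference time point 1 to target time point 1; every subsequent
#' reference time point is matched to the target time point with the
#' minimum distance among those not earlier than the previous match (no
#' steps backward in time), ties broken toward the earliest time point.
#' The per-step exhaustive scan over admissible columns is the whole
#' algorithm. Several reference time points may share one target time
#' point.
#'
#' @param distMatrix finite numeric matrix (reference x target cohorts),
#'   e.g. from [profileDistanceMatrix()].
#' @return a [TimepointMatching].
#' @export
matchTimepoints <- function(distMatrix) {
  stopifnot(is.matrix(distMatrix), all(is.finite(distMatrix)),
            nrow(distMatrix) >= 1L, ncol(distMatrix) >= 1L)
  nr <- nrow(distMatrix); nc <- ncol(distMatrix)
  path <- integer(nr)
  path[1] <- 1L
  for (t in seq_len(nr)[-1]) {
    cols <- seq.int(path[t - 1L], nc)
    path[t] <- cols[which.min(distMatrix[t, cols])]
  }
  new("TimepointMatching", distMatrix = distMatrix, path = path)
}

#' Hourglass divergence curve
#'
#' Per cohort, the Euclidean distances between the cell-type proportion
#' vectors of all unordered species pairs (n species give
#' `choose(n, 2)` comparisons per time point), summarised as mean and
#' standard error of the mean.
#'
#' @param profiles list of >= 2 [CellTypeProfile] objects over one gene
#'   universe (e.g. from [enumerateCellTypes()]).
#' @return data.frame with columns `cohort`, `mean`, `sem`, `nPairs`.
#' @export
hourglassCurve <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  ns <- length(profiles)
  nt <- ncol(profiles[[1]]@proportions)
  pairD <- list()
  for (i in seq_len(ns - 1L)) for (j in seq.int(i + 1L, ns)) {
    dm <- profileDistanceMatrix(profiles[[i]], profiles[[j]])
    pairD[[length(pairD) + 1L]] <- diag(dm)
  }
  D <- do.call(rbind, pairD) # pairs x cohorts
  data.frame(cohort = seq_len(nt),
             mean = colMeans(D),
             sem = apply(D, 2, stats::sd) / sqrt(nrow(D)),
             nPairs = nrow(D))
}
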
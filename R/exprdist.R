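## Expression distance scores between species atlases. Each cell is a
## vector of mean expression over all panel genes and all six cohorts;
## two cells are compared by the squared Euclidean distance
## D(i,j) = sum_{g,t} (E(i,g,t) - E(j,g,t))^2, which is additive across
## genes and time points. Spatial correspondence uses coordinates scaled
## to unit egg length and centered on the center of mass.

#' Scale expression so each gene's per-cohort maximum is 1
#'
#' Per gene and cohort, divides by the maximum over nuclei. All-zero
#' gene-cohorts are left unchanged with a warning.
#'
#' @param atlas an [Atlas].
#' @return the normalized [Atlas].
#' @export
normalizeExpression <- function(atlas) {
  stopifnot(is(atlas, "Atlas"))
  for (t in seq_along(atlas@E)) {
    mx <- apply(atlas@E[[t]], 2, max)
    zero <- mx <= 0
    if (any(zero))
      warning("all-zero gene-cohort(s) left unscaled: ",
              paste(colnames(atlas@E[[t]])[zero], collapse = ", "),
              " (cohort ", t, ")")
    mx[zero] <- 1
    atlas@E[[t]] <- sweep(atlas@E[[t]], 2, mx, "/")
  }
  atlas
}

#' Per-cell expression profiles across genes and cohorts
#'
#' Builds the n x (genes x cohorts) profile matrix anchored at the nuclei
#' of `anchor` cohort (default the final one), following the cross-cohort
#' correspondence maps backwards/forwards to collect each cell's values at
#' every requested cohort. Errors if any anchored nucleus cannot be
#' tracked through all requested cohorts.
#'
#' @param atlas an [Atlas].
#' @param genes gene panel (default all).
#' @param cohorts cohorts to include (default 1:6).
#' @param anchor cohort whose nuclei index the rows (default 6).
#' @return numeric matrix with columns named `<gene>@t<cohort>`.
#' @export
expressionProfiles <- function(atlas, genes = NULL, cohorts = 1:6,
                               anchor = 6L) {
  stopifnot(is(atlas, "Atlas"))
  if (is.null(genes)) genes <- atlas@genes
  missing <- setdiff(genes, atlas@genes)
  if (length(missing))
    stop("gene(s) not in atlas: ", paste(missing, collapse = ", "))
  nt <- length(atlas@E)
  stopifnot(all(cohorts >= 1L), all(cohorts <= nt), anchor %in% 1:nt)
  n <- nrow(atlas@E[[anchor]])
  # index of each anchored nucleus in every cohort
  idx <- matrix(NA_integer_, n, nt)
  idx[, anchor] <- seq_len(n)
  if (anchor < nt) for (t in seq(anchor, nt - 1L))
    idx[, t + 1L] <- atlas@correspondence[[t]][idx[, t]]
  if (anchor > 1L) for (t in seq(anchor - 1L, 1L))
    idx[, t] <- match(idx[, t + 1L], atlas@correspondence[[t]])
  if (anyNA(idx[, cohorts]))
    stop("some nuclei cannot be tracked through all requested cohorts")
  cols <- as.vector(outer(genes, cohorts, function(g, t)
    paste0(g, "@t", t)))
  P <- matrix(NA_real_, n, length(genes) * length(cohorts),
              dimnames = list(NULL, cols))
  for (ci in seq_along(cohorts)) {
    t <- cohorts[ci]
    P[, (ci - 1L) * length(genes) + seq_along(genes)] <-
      atlas@E[[t]][idx[, t], genes, drop = FALSE]
  }
  P
}

#' Squared Euclidean expression distance
#'
#' `D = sum((x - y)^2)` over matched entries of two expression profile
#' vectors; symmetric, non-negative, zero iff the profiles are equal, and
#' additive across disjoint gene/cohort blocks.
#'
#' @param x,y numeric profile vectors of equal length (no missing values).
#' @return numeric(1).
#' @export
expressionDistance <- function(x, y) {
  if (length(x) != length(y))
    stop("profiles have different lengths")
  if (anyNA(x) || anyNA(y)) stop("profiles contain missing values")
  sum((x - y)^2)
}

## scaled, centered coordinates of one cohort (unit egg length)
.scaledCoords <- function(atlas, cohort = 6L) {
  p <- atlas@positions[[cohort]]
  p <- p / atlas@eggLength
  sweep(p, 2, colMeans(p))
}

#' Nearest spatial match between two atlases
#'
#' Coordinates of each atlas (at `cohort`, default the final one) are
#' scaled to unit egg length and centered on the center of mass; each
#' reference nucleus is matched to the nearest target nucleus by Euclidean
#' distance in that scaled space.
#'
#' @param ref,target [Atlas] objects (normalize first for comparable D).
#' @param cohort cohort whose coordinates define positions (default 6).
#' @return data.frame with `query_index`, `target_index`,
#'   `spatial_eucl` (scaled-space distance).
#' @export
spatialMatch <- function(ref, target, cohort = 6L) {
  stopifnot(is(ref, "Atlas"), is(target, "Atlas"))
  q <- .scaledCoords(ref, cohort)
  x <- .scaledCoords(target, cohort)
  if (!nrow(q) || !nrow(x)) stop("empty atlas")
  nn <- .knn(x, q, 1L)
  data.frame(query_index = seq_len(nrow(q)),
             target_index = nn$idx[, 1],
             spatial_eucl = nn$dist[, 1])
}

#' Local best-match expression distances and weighted displacements
#'
#' For every reference nucleus: `spatial_dist` is the expression distance
#' D to its nearest spatial neighbor in the target; the candidate set is
#' the `k` target nuclei nearest (in scaled, centered space) to the
#' query's mapped position; `local_best_dist` is the minimum D over the
#' candidates (evaluated exhaustively). The matched location is the
#' average of the 3D positions of the `m` candidates with smallest D,
#' weighted by 1/(D + eps); candidates with D exactly 0 are averaged
#' uniformly. Displacements are reported in target-atlas um
#' (`scaled = TRUE` gives egg-length units in the shared scaled frame).
#'
#' @param ref,target normalized [Atlas] objects.
#' @param genes gene panel (default: genes shared by both atlases).
#' @param cohorts cohorts entering D (default 1:6).
#' @param k candidate neighborhood size (default 30). If the target is
#'   smaller than `k`, all nuclei are used with a warning.
#' @param m matches averaged for the displacement (default 10).
#' @param cohort cohort defining spatial positions (default 6).
#' @param scaled report displacements in scaled egg-length units.
#' @param eps inverse-distance weight regulariser (default 1e-12).
#' @return a [MatchResult]; its table has columns `query_index`,
#'   `target_index`, `spatial_eucl`, `spatial_dist`, `local_best_dist`,
#'   `local_best_index`, `disp_x/y/z`, `target_x/y/z`.
#' @export
localBestMatch <- function(ref, target, genes = NULL, cohorts = 1:6,
                           k = 30L, m = 10L, cohort = 6L, scaled = FALSE,
                           eps = 1e-12) {
  stopifnot(is(ref, "Atlas"), is(target, "Atlas"))
  if (is.null(genes)) genes <- intersect(ref@genes, target@genes)
  if (!length(genes)) stop("no shared genes between the atlases")
  Pr <- expressionProfiles(ref, genes, cohorts, anchor = cohort)
  Pt <- expressionProfiles(target, genes, cohorts, anchor = cohort)
  q <- .scaledCoords(ref, cohort)
  x <- .scaledCoords(target, cohort)
  if (k > nrow(x)) {
    warning("target atlas smaller than k = ", k, "; using all ",
            nrow(x), " nuclei")
    k <- nrow(x)
  }
  nn <- .knn(x, q, k)
  n <- nrow(q)
  sq <- rowSums(Pt^2)
  spatialD <- rowSums((Pr - Pt[nn$idx[, 1], , drop = FALSE])^2)
  bestD <- numeric(n); bestIdx <- integer(n)
  disp <- matrix(0, n, 3); tgt <- matrix(0, n, 3)
  posT <- if (scaled) x else target@positions[[cohort]]
  posQ <- if (scaled) q else {
    # query position mapped into target um space via the shared scaled frame
    sweep(q * target@eggLength, 2,
          -colMeans(target@positions[[cohort]]), "-")
  }
  mm <- min(m, k)
  for (i in seq_len(n)) {
    cand <- nn$idx[i, ]
    D <- sq[cand] - 2 * drop(Pt[cand, , drop = FALSE] %*% Pr[i, ]) +
      sum(Pr[i, ]^2)
    D[D < 0] <- 0 # numerical floor
    j <- which.min(D)
    bestD[i] <- D[j]
    bestIdx[i] <- cand[j]
    ord <- order(D)[seq_len(mm)]
    Dm <- D[ord]
    w <- if (any(Dm == 0)) as.numeric(Dm == 0) else 1 / (Dm + eps)
    loc <- colSums(posT[cand[ord], , drop = FALSE] * w) / sum(w)
    tgt[i, ] <- loc
    disp[i, ] <- loc - posQ[i, ]
  }
  spatialD <- pmax(spatialD, bestD) # guard float noise: best <= spatial
  tb <- data.frame(query_index = seq_len(n), target_index = nn$idx[, 1],
                   spatial_eucl = nn$dist[, 1], spatial_dist = spatialD,
                   local_best_dist = bestD, local_best_index = bestIdx,
                   disp_x = disp[, 1], disp_y = disp[, 2],
                   disp_z = disp[, 3], target_x = tgt[, 1],
                   target_y = tgt[, 2], target_z = tgt[, 3])
  new("MatchResult", refSpecies = ref@species,
      targetSpecies = target@species, k = as.integer(k),
      m = as.integer(mm), table = tb)
}

#' Inverse-distance-weighted displacement for one candidate set
#'
#' The matched location is `sum(w_c x_c) / sum(w_c)` over the `m`
#' candidates with smallest expression distance, `w_c = 1/(D_c + eps)`;
#' if any candidate has D exactly 0, the zero-D candidates are averaged
#' uniformly. Exposed for oracle-style testing and custom pipelines;
#' [localBestMatch()] applies it per nucleus.
#'
#' @param D numeric vector of candidate expression distances.
#' @param pos candidate positions (length(D) x 3).
#' @param query query position (numeric(3)).
#' @param m number of best candidates to average (default 10).
#' @param eps weight regulariser.
#' @return list with `target` (numeric(3)) and `displacement`
#'   (numeric(3), `target - query`).
#' @export
weightedDisplacement <- function(D, pos, query, m = 10L, eps = 1e-12) {
  stopifnot(length(D) >= 1L, nrow(pos) == length(D), length(query) == 3L)
  ord <- order(D)[seq_len(min(m, length(D)))]
  Dm <- D[ord]
  w <- if (any(Dm == 0)) as.numeric(Dm == 0) else 1 / (Dm + eps)
  loc <- colSums(pos[ord, , drop = FALSE] * w) / sum(w)
  list(target = loc, displacement = loc - query)
}

#' Cylindrical-projection displacement table
#'
#' Per-nucleus rows for quiver-style visualisation of the displacement
#' field: the reference nucleus's cylindrical coordinates, the
#' displacement components, the 3D magnitude (which may exceed the length
#' of the arrow in the 2D projection), and the in-projection direction.
#'
#' @param result a [MatchResult] from [localBestMatch()].
#' @param ref the reference [Atlas] used for the match.
#' @param cohort cohort defining positions (default 6).
#' @return data.frame with columns `ap`, `phi`, `d_ap` (egg-length
#'   fraction), `magnitude` (um, 3D), `direction` (radians in the
#'   (AP, phi) projection plane).
#' @export
displacementField <- function(result, ref, cohort = 6L) {
  stopifnot(is(result, "MatchResult"), is(ref, "Atlas"))
  tb <- result@table
  if (!nrow(tb)) stop("empty match result")
  cyl <- cylindricalCoords(ref, cohort = cohort)
  axc <- .apAxis(ref@positions[[cohort]], anterior = ref@metadata$anterior)
  disp <- as.matrix(tb[, c("disp_x", "disp_y", "disp_z")])
  dAxial <- drop(disp %*% axc$axis)
  magnitude <- sqrt(rowSums(disp^2))
  # angular component from the change in phi implied by the displacement
  dTrans <- sqrt(pmax(magnitude^2 - dAxial^2, 0))
  data.frame(ap = cyl$ap, phi = cyl$phi,
             d_ap = dAxial / ref@eggLength,
             magnitude = magnitude,
             direction = atan2(dTrans, dAxial))
}
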
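#' @import methods
NULL

## Central containers. All positions are in micrometres (um); expression
## levels are arbitrary fluorescence units >= 0. Developmental time is
## discretised into 6 cohorts by percent membrane invagination.

#' Pointcloud: one imaged embryo
#'
#' A `Pointcloud` holds one embryo's nuclei: 3D coordinates (um), per-gene
#' fluorescence levels, and the nucleus neighbor relation that defines the
#' surface triangulation. The neighbor relation is stored symmetrically:
#' `j %in% neighbors(pc)[[i]]` implies `i %in% neighbors(pc)[[j]]`.
#'
#' @slot species character(1), species label.
#' @slot stage numeric(1), percent membrane invagination in [0, 100].
#' @slot cohort integer(1), time cohort 1..6; must agree with `stage`
#'   under [cohortFromStage()].
#' @slot coords n x 3 numeric matrix of nucleus positions (um).
#' @slot expr n x g numeric matrix of expression levels, finite and
#'   non-negative, with gene names as column names.
#' @slot neighbors list of length n; integer vectors of neighbor indices.
#' @slot metadata list; recognised entries include `dorsal` and `anterior`
#'   (unit 3-vectors fixing the cylindrical frame) and generator ground truth.
#'
#' @seealso [readPointcloud()], [writePointcloud()], [cylindricalCoords()]
#' @export
setClass("Pointcloud",
  representation(
    species = "character",
    stage = "numeric",
    cohort = "integer",
    coords = "matrix",
    expr = "matrix",
    neighbors = "list",
    metadata = "list"
  ),
  prototype(
    species = NA_character_, stage = 0, cohort = 1L,
    coords = matrix(numeric(0), 0, 3), expr = matrix(numeric(0), 0, 0),
    neighbors = list(), metadata = list()
  )
)

setValidity("Pointcloud", function(object) {
  msg <- character(0)
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must have 3 columns (x, y, z)")
  if (nrow(object@expr) != n)
    msg <- c(msg, "expr must have one row per nucleus")
  if (ncol(object@expr) > 0L && is.null(colnames(object@expr)))
    msg <- c(msg, "expr columns must be named by gene")
  if (any(!is.finite(object@expr)))
    msg <- c(msg, "expression levels must be finite")
  else if (any(object@expr < 0))
    msg <- c(msg, "expression levels must be non-negative")
  if (length(object@neighbors) != n)
    msg <- c(msg, "neighbors must have one entry per nucleus")
  if (length(object@stage) != 1L || object@stage < 0 || object@stage > 100)
    msg <- c(msg, "stage must be a single value in [0, 100]")
  if (length(object@cohort) != 1L || object@cohort < 1L || object@cohort > 6L)
    msg <- c(msg, "cohort must be a single integer in 1..6")
  else if (length(object@stage) == 1L && object@stage >= 0 &&
           object@stage <= 100 &&
           object@cohort != cohortFromStage(object@stage))
    msg <- c(msg, sprintf("cohort %d inconsistent with stage %.1f%%",
                          object@cohort, object@stage))
  if (length(object@neighbors) == n && n > 0L) {
    ok <- .neighborsSymmetric(object@neighbors)
    if (!isTRUE(ok)) msg <- c(msg, ok)
  }
  if (length(msg)) msg else TRUE
})

#' Atlas: species-level averaged expression over six time cohorts
#'
#' An `Atlas` stores, for one species, the average nucleus positions and the
#' mean expression of each gene in each nucleus at each of the six time
#' cohorts, an optional matching standard-deviation tensor, and the
#' injective nucleus correspondence between consecutive cohorts.
#'
#' @slot species character(1).
#' @slot genes character vector, the ordered gene panel.
#' @slot positions list of 6 matrices (n_t x 3), nucleus positions (um).
#' @slot E list of 6 matrices (n_t x g), mean expression; finite,
#'   non-negative where defined.
#' @slot S list of 6 matrices (n_t x g) of inter-embryo standard deviations,
#'   or an empty list when unavailable.
#' @slot correspondence list of 5 integer vectors; element t maps nucleus
#'   index in cohort t to its index in cohort t+1 (NA where untracked);
#'   injective on non-NA entries.
#' @slot eggLength numeric(1), embryo extent along the AP axis (um).
#' @slot metadata list (dorsal/anterior frame vectors, ground truth, ...).
#' @export
setClass("Atlas",
  representation(
    species = "character",
    genes = "character",
    positions = "list",
    E = "list",
    S = "list",
    correspondence = "list",
    eggLength = "numeric",
    metadata = "list"
  )
)

setValidity("Atlas", function(object) {
  msg <- character(0)
  nt <- length(object@positions)
  if (nt != 6L) msg <- c(msg, "an Atlas must have 6 time cohorts")
  if (length(object@E) != nt) msg <- c(msg, "E must have one slice per cohort")
  for (t in seq_len(min(nt, length(object@E)))) {
    if (nrow(object@positions[[t]]) == 0L)
      msg <- c(msg, sprintf("cohort %d has no nuclei", t))
    if (nrow(object@E[[t]]) != nrow(object@positions[[t]]))
      msg <- c(msg, sprintf("cohort %d: E rows != nucleus count", t))
    if (ncol(object@E[[t]]) != length(object@genes))
      msg <- c(msg, sprintf("cohort %d: E columns != gene panel", t))
    e <- object@E[[t]]
    if (any(!is.finite(e) & !is.na(e)) || any(e < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("cohort %d: E must be finite and non-negative", t))
  }
  if (length(object@S) && length(object@S) != nt)
    msg <- c(msg, "S, when present, must have one slice per cohort")
  if (length(object@correspondence) &&
      length(object@correspondence) != nt - 1L)
    msg <- c(msg, "correspondence must link consecutive cohort pairs")
  for (t in seq_along(object@correspondence)) {
    m <- object@correspondence[[t]]
    if (length(m) != nrow(object@positions[[t]]))
      msg <- c(msg, sprintf("correspondence %d has wrong length", t))
    mm <- m[!is.na(m)]
    if (anyDuplicated(mm))
      msg <- c(msg, sprintf("correspondence %d is not injective", t))
  }
  if (length(object@eggLength) != 1L || !is.finite(object@eggLength) ||
      object@eggLength <= 0)
    msg <- c(msg, "eggLength must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' BinaryCalls: on/off expression calls
#'
#' Threshold-based binary calls per nucleus x gene x cohort for one species,
#' together with the per-(gene, cohort) thresholds that produced them.
#' A nucleus is "on" iff its expression is strictly greater than the
#' threshold for that gene and cohort.
#'
#' @slot species character(1).
#' @slot genes character vector (panel used).
#' @slot calls list of 6 logical matrices (n_t x g).
#' @slot thresholds g x 6 numeric matrix.
#' @export
setClass("BinaryCalls",
  representation(species = "character", genes = "character",
                 calls = "list", thresholds = "matrix")
)

setValidity("BinaryCalls", function(object) {
  msg <- character(0)
  if (length(object@calls) != ncol(object@thresholds))
    msg <- c(msg, "one threshold column per cohort required")
  if (nrow(object@thresholds) != length(object@genes))
    msg <- c(msg, "one threshold row per gene required")
  for (t in seq_along(object@calls)) {
    cm <- object@calls[[t]]
    if (!is.logical(cm) || ncol(cm) != length(object@genes))
      msg <- c(msg, sprintf("cohort %d: calls must be logical n x g", t))
  }
  if (length(msg)) msg else TRUE
})

#' CellTypeProfile: cell-type proportion vectors for one species
#'
#' A cell type is the subset of panel genes called "on" in a nucleus at a
#' time point. The profile stores, per cohort, the fraction of nuclei
#' falling into each retained cell type. Proportions are computed over all
#' nuclei and are not renormalised after rare-combination filtering, so
#' columns may sum to slightly less than 1.
#'
#' @slot species character(1).
#' @slot universe character vector, the gene panel.
#' @slot types character vector of type labels ("" is the all-off type;
#'   otherwise on-genes joined by "+").
#' @slot proportions types x cohorts numeric matrix in [0, 1].
#' @export
setClass("CellTypeProfile",
  representation(species = "character", universe = "character",
                 types = "character", proportions = "matrix")
)

setValidity("CellTypeProfile", function(object) {
  msg <- character(0)
  p <- object@proportions
  if (nrow(p) != length(object@types))
    msg <- c(msg, "one proportion row per cell type required")
  if (any(p < 0) || any(p > 1))
    msg <- c(msg, "proportions must lie in [0, 1]")
  if (ncol(p) > 0 && any(colSums(p) > 1 + 1e-8))
    msg <- c(msg, "per-cohort proportions cannot exceed 1 in total")
  if (length(msg)) msg else TRUE
})

#' MatchResult: expression-distance matches between two atlases
#'
#' Per reference-nucleus results of spatial matching and local best-match
#' search against a target atlas: the expression distance to the nearest
#' spatial neighbor, the minimum distance over the k-nearest candidate
#' neighborhood, and the inverse-distance-weighted displacement to the
#' best-matching location.
#'
#' @slot refSpecies,targetSpecies character(1).
#' @slot k integer(1), candidate neighborhood size.
#' @slot m integer(1), number of best matches averaged for displacement.
#' @slot table data.frame, one row per reference nucleus (see
#'   [localBestMatch()]).
#' @export
setClass("MatchResult",
  representation(refSpecies = "character", targetSpecies = "character",
                 k = "integer", m = "integer", table = "data.frame")
)

setValidity("MatchResult", function(object) {
  tb <- object@table
  need <- c("query_index", "spatial_dist", "local_best_dist")
  if (!all(need %in% names(tb)))
    return("table must contain query_index, spatial_dist, local_best_dist")
  bad <- tb$local_best_dist > tb$spatial_dist + 1e-12
  if (any(bad, na.rm = TRUE))
    return("local_best_dist may not exceed spatial_dist")
  if (any(!is.finite(tb$spatial_dist)) || any(!is.finite(tb$local_best_dist)))
    return("distances must be finite")
  TRUE
})

#' TimepointMatching: monotone developmental time-point map
#'
#' The 6 x 6 (more generally n x m) matrix of Euclidean distances between
#' cell-type proportion vectors of a reference and a target species, and the
#' greedy monotone path through it: path(1) = 1 and each subsequent
#' reference cohort is matched to the minimum-distance target cohort not
#' earlier than the previous match.
#'
#' @slot distMatrix numeric matrix, reference cohorts x target cohorts.
#' @slot path integer vector, target cohort matched to each reference cohort.
#' @export
setClass("TimepointMatching",
  representation(distMatrix = "matrix", path = "integer")
)

setValidity("TimepointMatching", function(object) {
  msg <- character(0)
  if (length(object@path) != nrow(object@distMatrix))
    msg <- c(msg, "path must have one entry per reference cohort")
  if (length(object@path)) {
    if (object@path[1] != 1L) msg <- c(msg, "path must start at cohort 1")
    if (any(diff(object@path) < 0L))
      msg <- c(msg, "path must be monotone non-decreasing")
    if (any(object@path < 1L | object@path > ncol(object@distMatrix)))
      msg <- c(msg, "path entries must be valid target cohorts")
  }
  if (length(msg)) msg else TRUE
})

#' DensityMap: cohort-averaged nuclear density on a cylindrical grid
#'
#' Local nuclear densities mapped into cylindrical coordinates (AP fraction
#' of egg length x angle around the AP axis), resampled to a regular grid
#' and averaged over the embryos of one cohort.
#'
#' @slot ap numeric vector of grid-cell AP centers in [0, 1].
#' @slot phi numeric vector of grid-cell angular centers in [-pi, pi).
#' @slot values ap x phi matrix, nuclei per um^2 (>= 0).
#' @slot cohort integer(1).
#' @slot nEmbryos integer(1), number of embryos averaged.
#' @export
setClass("DensityMap",
  representation(ap = "numeric", phi = "numeric", values = "matrix",
                 cohort = "integer", nEmbryos = "integer")
)

setValidity("DensityMap", function(object) {
  msg <- character(0)
  if (!all(dim(object@values) == c(length(object@ap), length(object@phi))))
    msg <- c(msg, "values must be ap x phi")
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "densities must be non-negative")
  if (any(object@phi < -pi - 1e-9) || any(object@phi >= pi + 1e-9))
    msg <- c(msg, "phi grid must cover [-pi, pi)")
  if (length(msg)) msg else TRUE
})

## -- internal helpers used by validity ------------------------------------

.neighborsSymmetric <- function(nb) {
  n <- length(nb)
  for (i in seq_len(n)) {
    v <- nb[[i]]
    if (length(v) == 0L) next
    if (any(v < 1L | v > n))
      return(sprintf("nucleus %d has out-of-range neighbor ids", i))
    for (j in v) if (!any(nb[[j]] == i))
      return(sprintf("neighbor relation not symmetric: %d -> %d", i, j))
  }
  TRUE
}
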
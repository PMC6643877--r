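#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers. Slot access via
#' `@` is considered internal; use these instead.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return The corresponding slot content (see method documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("species", function(x) standardGeneric("species"))

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x, ...) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("neighbors", function(x) standardGeneric("neighbors"))

#' @rdname accessors
#' @export
setGeneric("nNuclei", function(x, ...) standardGeneric("nNuclei"))

#' @rdname accessors
#' @export
setGeneric("cohort", function(x) standardGeneric("cohort"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("callMatrix", function(x, cohort) standardGeneric("callMatrix"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))

#' @rdname accessors
#' @export
setGeneric("distMatrix", function(x) standardGeneric("distMatrix"))

#' @rdname accessors
#' @export
setGeneric("warpPath", function(x) standardGeneric("warpPath"))

#' @rdname accessors
#' @export
setGeneric("matchTable", function(x) standardGeneric("matchTable"))

#' Egg length of an embryo or atlas
#'
#' Extent of the nucleus cloud along its first principal axis, in um.
#' For an `Atlas` the stored egg length (derived from the final cohort at
#' construction) is returned unless `recompute = TRUE`.
#'
#' @param x a `Pointcloud` or `Atlas`.
#' @param ... method arguments (`cohort`, `recompute`).
#' @return numeric(1), egg length in um.
#' @export
setGeneric("eggLength", function(x, ...) standardGeneric("eggLength"))

#' Cylindrical coordinates on the embryo surface
#'
#' Projects on-surface nuclei into the atlas cylindrical coordinate system:
#' `ap`, the position along the anterior-posterior axis as a fraction of egg
#' length in [0, 1] (anterior = 0), and `phi`, the angle (radians, in
#' [-pi, pi)) around the AP axis with phi = 0 at the dorsal midline and
#' increasing through left (+pi/2), ventral (+/-pi) and right (-pi/2).
#'
#' The AP axis is the first principal component of the nucleus coordinates;
#' its sign is fixed by an `anterior` metadata vector when present. The
#' dorsal reference comes from the `dorsal` metadata vector (always recorded
#' by the synthetic generator) or from the `dorsal` argument.
#'
#' @param x a `Pointcloud`, `Atlas`, or n x 3 coordinate matrix.
#' @param ... method arguments (`cohort` for atlases; `dorsal`, `anterior`
#'   overrides).
#' @return data.frame with columns `ap` and `phi`.
#' @export
setGeneric("cylindricalCoords", function(x, ...)
  standardGeneric("cylindricalCoords"))
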
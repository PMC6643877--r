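## Cylindrical projection of the blastoderm surface.
##
## The AP axis is the first principal component of the nucleus coordinates.
## ap is the normalized projection (min -> 0 anterior, max -> 1 posterior).
## phi is measured in the plane orthogonal to the axis, with phi = 0 at the
## dorsal midline, +pi/2 left, +/-pi ventral, -pi/2 right, so an unrolled
## map read top-to-bottom in increasing phi shows rows D, L, V, R.

.cylindrical <- function(coords, dorsal = NULL, anterior = NULL) {
  axc <- .apAxis(coords, anterior = anterior)
  u <- axc$axis
  centered <- sweep(coords, 2, axc$center)
  s <- drop(centered %*% u)
  rng <- range(s)
  if (diff(rng) <= 0) stop("degenerate geometry: zero AP extent")
  ap <- (s - rng[1]) / diff(rng)
  if (is.null(dorsal))
    stop("no dorsal reference: supply `dorsal` or record it in metadata")
  d <- dorsal - sum(dorsal * u) * u
  if (sqrt(sum(d^2)) < 1e-9)
    stop("dorsal reference is parallel to the AP axis")
  d <- .unit(d)
  l <- .cross(d, u) # 'left' direction; fixes the handedness of phi
  radial <- centered - outer(s, u)
  phi <- atan2(drop(radial %*% l), drop(radial %*% d))
  phi[phi >= pi] <- phi[phi >= pi] - 2 * pi
  data.frame(ap = ap, phi = phi)
}

#' @describeIn cylindricalCoords project a Pointcloud's nuclei; `dorsal` and
#'   `anterior` default to the pointcloud metadata.
#' @param dorsal numeric(3) dorsal reference direction (required if absent
#'   from metadata).
#' @param anterior numeric(3) optional anterior direction fixing the AP sign.
#' @export
setMethod("cylindricalCoords", "Pointcloud",
  function(x, dorsal = x@metadata$dorsal, anterior = x@metadata$anterior,
           ...) {
    .cylindrical(x@coords, dorsal = dorsal, anterior = anterior)
  })

#' @describeIn cylindricalCoords project one atlas cohort.
#' @param cohort integer cohort in 1..6 (default 6).
#' @export
setMethod("cylindricalCoords", "Atlas",
  function(x, cohort = 6L, dorsal = x@metadata$dorsal,
           anterior = x@metadata$anterior, ...) {
    stopifnot(cohort >= 1L, cohort <= length(x@positions))
    .cylindrical(x@positions[[cohort]], dorsal = dorsal, anterior = anterior)
  })

#' @describeIn cylindricalCoords project a raw n x 3 coordinate matrix.
#' @export
setMethod("cylindricalCoords", "matrix",
  function(x, dorsal = NULL, anterior = NULL, ...) {
    .cylindrical(x, dorsal = dorsal, anterior = anterior)
  })

#' @describeIn eggLength extent of a Pointcloud along its AP axis.
#' @export
setMethod("eggLength", "Pointcloud", function(x, ...) {
  axc <- .apAxis(x@coords, anterior = x@metadata$anterior)
  s <- drop(sweep(x@coords, 2, axc$center) %*% axc$axis)
  diff(range(s))
})

#' @describeIn eggLength stored egg length of an Atlas; with
#'   `recompute = TRUE`, the AP extent of cohort `cohort` positions.
#' @param cohort integer cohort used when recomputing (default 6).
#' @param recompute logical; recompute from coordinates instead of the
#'   stored value.
#' @export
setMethod("eggLength", "Atlas", function(x, cohort = 6L, recompute = FALSE,
                                         ...) {
  if (!recompute) return(x@eggLength)
  p <- x@positions[[cohort]]
  axc <- .apAxis(p, anterior = x@metadata$anterior)
  s <- drop(sweep(p, 2, axc$center) %*% axc$axis)
  diff(range(s))
})

#' Embryo shape profile along the AP axis
#'
#' Summarises the embryo outline: per AP bin, the mean radial distance of
#' nuclei from the AP axis (cross-sectional radius) and the extreme dorsal
#' and ventral offsets (lateral outline), all in um.
#'
#' @param pc a `Pointcloud`.
#' @param nBins number of AP bins (default 50).
#' @param dorsal,anterior frame overrides (default: pointcloud metadata).
#' @return data.frame with columns `ap` (bin center, fraction of egg
#'   length), `radius`, `dorsalExtent`, `ventralExtent` (um; NA for empty
#'   bins).
#' @export
shapeProfile <- function(pc, nBins = 50L, dorsal = pc@metadata$dorsal,
                         anterior = pc@metadata$anterior) {
  stopifnot(is(pc, "Pointcloud"), nBins >= 2L)
  axc <- .apAxis(pc@coords, anterior = anterior)
  u <- axc$axis
  centered <- sweep(pc@coords, 2, axc$center)
  s <- drop(centered %*% u)
  ap <- (s - min(s)) / diff(range(s))
  radial <- centered - outer(s, u)
  r <- sqrt(rowSums(radial^2))
  if (is.null(dorsal)) stop("shapeProfile needs a dorsal reference")
  d <- .unit(dorsal - sum(dorsal * u) * u)
  dv <- drop(radial %*% d) # positive dorsal, negative ventral
  bin <- pmin(pmax(ceiling(ap * nBins), 1L), nBins)
  agg <- function(v, f) {
    out <- rep(NA_real_, nBins)
    got <- tapply(v, factor(bin, levels = seq_len(nBins)), f)
    out[!is.na(got)] <- got[!is.na(got)]
    out
  }
  data.frame(
    ap = (seq_len(nBins) - 0.5) / nBins,
    radius = agg(r, mean),
    dorsalExtent = agg(dv, max),
    ventralExtent = agg(dv, min)
  )
}
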
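#' @describeIn accessors species label of a Pointcloud.
setMethod("species", "Pointcloud", function(x) x@species)

#' @describeIn accessors species label of an Atlas.
setMethod("species", "Atlas", function(x) x@species)

#' @describeIn accessors species label of BinaryCalls.
setMethod("species", "BinaryCalls", function(x) x@species)

#' @describeIn accessors species label of a CellTypeProfile.
setMethod("species", "CellTypeProfile", function(x) x@species)

#' @describeIn accessors gene panel of a Pointcloud.
setMethod("genes", "Pointcloud", function(x) colnames(x@expr))

#' @describeIn accessors gene panel of an Atlas.
setMethod("genes", "Atlas", function(x) x@genes)

#' @describeIn accessors gene panel of BinaryCalls.
setMethod("genes", "BinaryCalls", function(x) x@genes)

#' @describeIn accessors gene universe of a CellTypeProfile.
setMethod("genes", "CellTypeProfile", function(x) x@universe)

#' @describeIn accessors nucleus coordinates (n x 3, um) of a Pointcloud.
setMethod("coords", "Pointcloud", function(x, ...) x@coords)

#' @describeIn accessors nucleus coordinates of one atlas cohort.
#' @param cohort integer cohort in 1..6.
setMethod("coords", "Atlas", function(x, cohort = 6L, ...) {
  stopifnot(cohort >= 1L, cohort <= length(x@positions))
  x@positions[[cohort]]
})

#' @describeIn accessors expression matrix (n x g) of a Pointcloud.
setMethod("exprValues", "Pointcloud", function(x, ...) x@expr)

#' @describeIn accessors mean-expression matrix of one atlas cohort.
setMethod("exprValues", "Atlas", function(x, cohort = 6L, ...) {
  stopifnot(cohort >= 1L, cohort <= length(x@E))
  x@E[[cohort]]
})

#' @describeIn accessors neighbor index lists of a Pointcloud.
setMethod("neighbors", "Pointcloud", function(x) x@neighbors)

#' @describeIn accessors nucleus count of a Pointcloud.
setMethod("nNuclei", "Pointcloud", function(x, ...) nrow(x@coords))

#' @describeIn accessors nucleus count of an atlas cohort.
setMethod("nNuclei", "Atlas", function(x, cohort = 6L, ...)
  nrow(x@positions[[cohort]]))

#' @describeIn accessors cohort of a Pointcloud.
setMethod("cohort", "Pointcloud", function(x) x@cohort)

#' @describeIn accessors per-(gene, cohort) thresholds of BinaryCalls.
setMethod("thresholds", "BinaryCalls", function(x) x@thresholds)

#' @describeIn accessors logical call matrix of one cohort.
setMethod("callMatrix", "BinaryCalls", function(x, cohort) {
  stopifnot(cohort >= 1L, cohort <= length(x@calls))
  x@calls[[cohort]]
})

#' @describeIn accessors cell-type labels of a CellTypeProfile.
setMethod("cellTypes", "CellTypeProfile", function(x) x@types)

#' @describeIn accessors proportion matrix (types x cohorts).
setMethod("proportions", "CellTypeProfile", function(x) x@proportions)

#' @describeIn accessors distance matrix of a TimepointMatching.
setMethod("distMatrix", "TimepointMatching", function(x) x@distMatrix)

#' @describeIn accessors monotone path of a TimepointMatching.
setMethod("warpPath", "TimepointMatching", function(x) x@path)

#' @describeIn accessors per-nucleus match table of a MatchResult.
setMethod("matchTable", "MatchResult", function(x) x@table)

## -- show methods ----------------------------------------------------------

setMethod("show", "Pointcloud", function(object) {
  cat(sprintf("Pointcloud: %s, cohort %d (%.1f%% invagination)\n",
              object@species, object@cohort, object@stage))
  cat(sprintf("  %d nuclei, %d genes: %s\n", nrow(object@coords),
              ncol(object@expr),
              paste(utils::head(colnames(object@expr), 10), collapse = ", ")))
  ne <- sum(lengths(object@neighbors)) / 2
  cat(sprintf("  %d neighbor edges\n", as.integer(ne)))
})

setMethod("show", "Atlas", function(object) {
  cat(sprintf("Atlas: %s, %d cohorts, egg length %.1f um\n",
              object@species, length(object@positions), object@eggLength))
  cat(sprintf("  nuclei per cohort: %s\n",
              paste(vapply(object@positions, nrow, 1L), collapse = ", ")))
  cat(sprintf("  %d genes: %s\n", length(object@genes),
              paste(object@genes, collapse = ", ")))
  cat(sprintf("  std tensor: %s; correspondence: %s\n",
              if (length(object@S)) "present" else "absent",
              if (length(object@correspondence)) "present" else "absent"))
})

setMethod("show", "BinaryCalls", function(object) {
  on <- vapply(object@calls, mean, 0)
  cat(sprintf("BinaryCalls: %s, %d genes x %d cohorts\n",
              object@species, length(object@genes), length(object@calls)))
  cat(sprintf("  fraction on per cohort: %s\n",
              paste(sprintf("%.3f", on), collapse = ", ")))
})

setMethod("show", "CellTypeProfile", function(object) {
  cat(sprintf("CellTypeProfile: %s, %d cell types over %d-gene panel\n",
              object@species, length(object@types), length(object@universe)))
  cat(sprintf("  per-cohort retained mass: %s\n",
              paste(sprintf("%.3f", colSums(object@proportions)),
                    collapse = ", ")))
})

setMethod("show", "MatchResult", function(object) {
  tb <- object@table
  cat(sprintf("MatchResult: %s -> %s (k = %d, m = %d), %d nuclei\n",
              object@refSpecies, object@targetSpecies, object@k, object@m,
              nrow(tb)))
  cat(sprintf("  median spatial D = %.4g, median local-best D = %.4g\n",
              stats::median(tb$spatial_dist),
              stats::median(tb$local_best_dist)))
})

setMethod("show", "TimepointMatching", function(object) {
  cat(sprintf("TimepointMatching: %d x %d distance matrix\n",
              nrow(object@distMatrix), ncol(object@distMatrix)))
  cat(sprintf("  path: %s\n", paste(object@path, collapse = " -> ")))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap: cohort %d, %d x %d grid, %d embryo(s)\n",
              object@cohort, length(object@ap), length(object@phi),
              object@nEmbryos))
  cat(sprintf("  density range %.4g - %.4g nuclei/um^2\n",
              min(object@values), max(object@values)))
})
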
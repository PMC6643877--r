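## Binary cell-type analysis. A gene is "on" in a nucleus when its level
## strictly exceeds a species- and time-point-specific threshold,
## mode(values) + sd(values), computed over all nuclei of that gene/cohort.
## A cell type is the subset of panel genes on in a nucleus; rare
## combinations (pooled frequency below 0.1% by default) are treated as
## measurement error and dropped.

#' Expression threshold: mode plus standard deviation
#'
#' The on/off threshold for one gene at one time point in one species is
#' the mode of the expression values plus their sample (n-1) standard
#' deviation. For near-continuous data the mode is estimated by a
#' 100-bin equal-width histogram over [min, max] (center of the fullest
#' bin, ties broken toward the lower bin); if more than half of the values
#' are exactly equal, that value is the mode.
#'
#' @param values numeric vector of expression levels (>= 2 values).
#' @param nBins histogram bins for the mode estimate (default 100).
#' @return numeric(1) threshold. All-identical input yields the common
#'   value (mode + 0) with a warning; under the strict ">" rule no nucleus
#'   is then on.
#' @examples
#' expressionThreshold(c(0.1, 0.1, 0.1, 0.5)) # 0.1 + 0.2 = 0.3
#' @export
expressionThreshold <- function(values, nBins = 100L) {
  stopifnot(length(values) >= 2L, all(is.finite(values)))
  if (min(values) == max(values)) {
    warning("all values identical; threshold equals the common value")
    return(values[1])
  }
  tab <- table(values)
  if (max(tab) > length(values) / 2) {
    mode <- as.numeric(names(tab)[which.max(tab)])
  } else {
    breaks <- seq(min(values), max(values), length.out = nBins + 1L)
    counts <- tabulate(findInterval(values, breaks,
                                    rightmost.closed = TRUE), nBins)
    b <- which.max(counts) # ties -> first, i.e. the lower bin
    mode <- (breaks[b] + breaks[b + 1L]) / 2
  }
  mode + stats::sd(values)
}

#' Binarize an atlas into on/off calls
#'
#' Applies [expressionThreshold()] per (gene, cohort) over all nuclei of
#' that cohort; a nucleus is on iff its mean level is strictly greater
#' than the threshold.
#'
#' @param atlas an [Atlas].
#' @param genes gene panel (default: all atlas genes). Missing genes are
#'   an error naming the gene.
#' @return a [BinaryCalls].
#' @export
binarize <- function(atlas, genes = NULL) {
  stopifnot(is(atlas, "Atlas"))
  if (is.null(genes)) genes <- atlas@genes
  missing <- setdiff(genes, atlas@genes)
  if (length(missing))
    stop("gene(s) not in atlas: ", paste(missing, collapse = ", "))
  nt <- length(atlas@E)
  thr <- matrix(NA_real_, length(genes), nt,
                dimnames = list(genes, seq_len(nt)))
  calls <- vector("list", nt)
  for (t in seq_len(nt)) {
    m <- atlas@E[[t]][, genes, drop = FALSE]
    cm <- matrix(FALSE, nrow(m), length(genes),
                 dimnames = list(NULL, genes))
    for (g in genes) {
      thr[g, t] <- suppressWarnings(expressionThreshold(m[, g]))
      cm[, g] <- m[, g] > thr[g, t]
    }
    calls[[t]] <- cm
  }
  new("BinaryCalls", species = atlas@species, genes = genes,
      calls = calls, thresholds = thr)
}

## per-nucleus cell-type labels for one call matrix ("" = all off)
.typeLabels <- function(cm, genes) {
  apply(cm, 1, function(r) paste(genes[r], collapse = "+"))
}

#' Enumerate cell types across species and filter rare combinations
#'
#' Assigns each nucleus x cohort its on-gene subset, pools subset
#' frequencies over all species, cohorts and nuclei, removes combinations
#' present in less than `minFrac` of the pooled nuclei (strictly below;
#' default 0.1%), and computes per-(species, cohort) proportion vectors
#' over all nuclei of the cohort. Proportions are not renormalised after
#' filtering. Set `scope = "per_species_cohort"` to filter within each
#' (species, cohort) instead of genus-wide.
#'
#' @param callsList a [BinaryCalls] or (named) list of them, one per
#'   species, sharing the same gene panel.
#' @param minFrac rare-combination threshold (default 0.001).
#' @param scope `"global"` (default) or `"per_species_cohort"`.
#' @return named list of [CellTypeProfile], one per species, indexed over
#'   the same ordered retained-type list.
#' @export
enumerateCellTypes <- function(callsList, minFrac = 0.001,
                               scope = c("global", "per_species_cohort")) {
  scope <- match.arg(scope)
  if (is(callsList, "BinaryCalls")) callsList <- list(callsList)
  stopifnot(length(callsList) >= 1L)
  panel <- genes(callsList[[1]])
  for (bc in callsList)
    if (!identical(genes(bc), panel))
      stop("all BinaryCalls must share one gene panel")
  labels <- lapply(callsList, function(bc)
    lapply(bc@calls, .typeLabels, genes = panel))
  all <- unlist(labels, use.names = FALSE)
  pooled <- table(all) / length(all)
  if (scope == "global") {
    keepSet <- names(pooled)[pooled >= minFrac]
  } else {
    keepSet <- character(0)
    for (sl in labels) for (lv in sl) {
      f <- table(lv) / length(lv)
      keepSet <- union(keepSet, names(f)[f >= minFrac])
    }
  }
  # order retained types by subset size, then by panel gene order
  sz <- vapply(strsplit(keepSet, "+", fixed = TRUE), length, 1L)
  sz[keepSet == ""] <- 0L
  ord <- order(sz, match(sub("\\+.*$", "", keepSet), panel), keepSet)
  types <- keepSet[ord]
  out <- vector("list", length(callsList))
  for (i in seq_along(callsList)) {
    nt <- length(labels[[i]])
    P <- matrix(0, length(types), nt,
                dimnames = list(types, seq_len(nt)))
    for (t in seq_len(nt)) {
      lv <- labels[[i]][[t]]
      f <- table(factor(lv, levels = types)) / length(lv)
      P[, t] <- as.numeric(f)
    }
    out[[i]] <- new("CellTypeProfile", species = species(callsList[[i]]),
                    universe = panel, types = types, proportions = P)
  }
  names(out) <- vapply(callsList, species, "")
  out
}

#' Cell-type combinatorics summary
#'
#' For each cell-type size k (number of on genes), the number of possible
#' subsets `choose(g, k)`, the number of observed (retained) types of that
#' size, and the percentage observed (2 significant digits, matching the
#' conventional table rounding).
#'
#' @param profiles output of [enumerateCellTypes()] (or one
#'   [CellTypeProfile]).
#' @return data.frame with columns `size`, `possible`, `observed`,
#'   `pctObserved`.
#' @export
cellTypeSummary <- function(profiles) {
  if (is(profiles, "CellTypeProfile")) profiles <- list(profiles)
  p1 <- profiles[[1]]
  g <- length(p1@universe)
  sz <- vapply(strsplit(p1@types, "+", fixed = TRUE), length, 1L)
  sz[p1@types == ""] <- 0L
  kmax <- max(c(sz, 0L))
  sizes <- 0:max(kmax, 0L)
  data.frame(
    size = sizes,
    possible = choose(g, sizes),
    observed = vapply(sizes, function(k) sum(sz == k), 1L),
    pctObserved = signif(vapply(sizes, function(k) sum(sz == k), 1L) /
                           choose(g, sizes) * 100, 2)
  )
}

#' Distribution of per-nucleus on-gene counts
#'
#' Per cohort, the proportion of nuclei expressing 0, 1, ..., k genes of a
#' panel (optionally a restricted sub-panel such as the eve/odd pair).
#'
#' @param calls a [BinaryCalls].
#' @param panel gene subset (default: all genes of `calls`).
#' @return (k+1) x cohorts matrix of proportions; each column sums to 1.
#' @export
geneCountDistribution <- function(calls, panel = NULL) {
  stopifnot(is(calls, "BinaryCalls"))
  if (is.null(panel)) panel <- calls@genes
  missing <- setdiff(panel, calls@genes)
  if (length(missing))
    stop("gene(s) not in calls: ", paste(missing, collapse = ", "))
  k <- length(panel)
  nt <- length(calls@calls)
  out <- matrix(0, k + 1L, nt,
                dimnames = list(0:k, seq_len(nt)))
  for (t in seq_len(nt)) {
    counts <- rowSums(calls@calls[[t]][, panel, drop = FALSE])
    out[, t] <- tabulate(counts + 1L, k + 1L) / length(counts)
  }
  out
}
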
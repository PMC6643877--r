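#' Time cohort from percent membrane invagination
#'
#' The blastoderm stage is divided into six time cohorts by percent membrane
#' invagination using half-open bins [0,4), [4,9), [9,26), [26,51), [51,76),
#' [76,100]; a stage of exactly 50% falls in cohort 4.
#'
#' @param stage numeric vector of percent invagination in [0, 100].
#' @return integer vector of cohorts in 1..6.
#' @examples
#' cohortFromStage(c(0, 3.9, 4, 25, 50, 75, 100))
#' @export
cohortFromStage <- function(stage) {
  stopifnot(all(is.finite(stage)), all(stage >= 0), all(stage <= 100))
  breaks <- c(0, 4, 9, 26, 51, 76)
  findInterval(stage, breaks)
}

## representative stage (bin midpoint) for a cohort, used by the generator
.stageForCohort <- function(cohort) {
  mid <- c(1.5, 6, 17, 38, 63, 88)
  mid[cohort]
}

#' Construct a Pointcloud
#'
#' Low-level constructor; validates all invariants (see
#' [Pointcloud-class]). The neighbor relation is symmetrized.
#'
#' @param coords n x 3 numeric matrix (um).
#' @param expr n x g numeric matrix with gene column names.
#' @param neighbors list of integer vectors (may be one-sided; symmetrized).
#' @param species,stage,cohort embryo annotation; `cohort` defaults to
#'   [cohortFromStage()] of `stage`.
#' @param metadata list of optional metadata (`dorsal`, `anterior`, ...).
#' @return a valid `Pointcloud`.
#' @export
Pointcloud <- function(coords, expr, neighbors = NULL,
                       species = "synthetic", stage = 0,
                       cohort = cohortFromStage(stage),
                       metadata = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  if (is.null(neighbors)) neighbors <- rep(list(integer(0)), nrow(coords))
  neighbors <- symmetrizeNeighbors(neighbors, nrow(coords))
  new("Pointcloud", species = species, stage = as.numeric(stage),
      cohort = as.integer(cohort), coords = coords, expr = expr,
      neighbors = neighbors, metadata = metadata)
}

#' Symmetrize a neighbor relation
#'
#' Ensures that whenever j is listed as a neighbor of i, i is also listed
#' as a neighbor of j. Entries are sorted and de-duplicated; self-edges are
#' dropped.
#'
#' @param neighbors list of integer vectors.
#' @param n number of nuclei (defaults to `length(neighbors)`).
#' @return list of sorted integer vectors with a symmetric relation.
#' @export
symmetrizeNeighbors <- function(neighbors, n = length(neighbors)) {
  from <- rep.int(seq_along(neighbors), lengths(neighbors))
  to <- as.integer(unlist(neighbors, use.names = FALSE))
  if (length(to) && (any(to < 1L) || any(to > n)))
    stop("neighbor ids out of range 1..", n)
  a <- c(from, to)
  b <- c(to, from)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  out <- rep(list(integer(0)), n)
  if (length(a)) {
    sp <- split(b, factor(a, levels = seq_len(n)))
    out <- lapply(sp, function(v) sort(unique(as.integer(v))))
  }
  unname(out)
}

## k-nearest-neighbor search (RANN kd-tree). Returns list(idx, dist):
## n_query x k matrices of data-row indices and Euclidean distances.
.knn <- function(data, query, k) {
  k <- min(k, nrow(data))
  res <- RANN::nn2(data, query, k = k)
  list(idx = res$nn.idx, dist = res$nn.dists)
}

## unit vector
.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-length direction vector")
  v / nv
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## principal AP axis of a coordinate cloud; sign fixed by `anterior` hint
## (axis points anterior -> posterior) or, failing that, so the largest
## absolute loading is positive.
.apAxis <- function(coords, anterior = NULL) {
  if (nrow(coords) < 3L) stop("need at least 3 nuclei to define an AP axis")
  pc <- stats::prcomp(coords, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] < 1e-9 || pc$sdev[2] / pc$sdev[1] < 1e-9)
    stop("degenerate geometry: nuclei are collinear")
  ax <- pc$rotation[, 1]
  if (!is.null(anterior)) {
    if (sum(ax * anterior) > 0) ax <- -ax
  } else if (ax[which.max(abs(ax))] < 0) {
    ax <- -ax
  }
  list(axis = ax, center = colMeans(coords))
}

## writes a data.frame as CSV with '#key=value' metadata header lines
.writeMetaCsv <- function(df, meta, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    writeLines(sprintf("#%s=%s", k, paste(format(v, digits = 15),
                                          collapse = ";")), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

## reads a '#key=value'-headed CSV; returns list(meta=list, data=data.frame)
.readMetaCsv <- function(path) {
  lines <- readLines(path)
  isMeta <- startsWith(lines, "#")
  nMeta <- match(FALSE, isMeta, nomatch = length(lines) + 1L) - 1L
  meta <- list()
  for (ln in lines[seq_len(nMeta)]) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- substr(kv, 1, eq - 1)
    val <- substr(kv, eq + 1, nchar(kv))
    parts <- strsplit(val, ";", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    meta[[key]] <- if (!anyNA(num)) num else val
  }
  body <- paste(lines[seq.int(nMeta + 1L, length(lines))], collapse = "\n")
  dat <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE,
                    check.names = FALSE),
    error = function(e) stop("malformed CSV in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  list(meta = meta, data = dat)
}
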
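## On-disk formats.
##
## Tabular pointcloud dialect: a CSV with optional '#key=value' metadata
## header lines (species, stage, cohort, dorsal, anterior as
## semicolon-separated numbers), then columns id, x, y, z, one column per
## gene, and a trailing `neighbors` column of semicolon-separated ids.
## Atlases are one such CSV per cohort (without neighbors, with optional
## `<gene>__sd` columns) plus correspondence CSVs and a meta file.
##
## BDTNP-style dialect: whitespace-delimited text with one column-header
## line; columns named x/y/z (case-insensitive) are coordinates, all other
## numeric columns are genes. Best effort; no neighbor information.

#' Read a pointcloud file
#'
#' @param path file path.
#' @param dialect `"tabular"` (the package CSV dialect) or `"bdtnp"`
#'   (whitespace-delimited with a column-header line).
#' @param unknownGenes for the tabular dialect, `"keep"` (default) keeps
#'   every non-reserved column as a gene; `"fail"` errors on genes not in
#'   `genePanel`; `"ignore"` drops them.
#' @param genePanel optional character vector of expected genes.
#' @return a valid [Pointcloud]; one-sided neighbor relations are
#'   symmetrized on read.
#' @seealso [writePointcloud()]
#' @export
readPointcloud <- function(path, dialect = c("tabular", "bdtnp"),
                           unknownGenes = c("keep", "fail", "ignore"),
                           genePanel = NULL) {
  dialect <- match.arg(dialect)
  unknownGenes <- match.arg(unknownGenes)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "bdtnp") return(.readBdtnp(path))
  md <- .readMetaCsv(path)
  dat <- md$data
  meta <- md$meta
  reserved <- c("id", "x", "y", "z", "neighbors")
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(dat)))
    stop("pointcloud CSV must have columns id, x, y, z; got: ",
         paste(names(dat), collapse = ", "))
  geneCols <- setdiff(names(dat), reserved)
  if (!is.null(genePanel)) {
    extra <- setdiff(geneCols, genePanel)
    if (length(extra) && unknownGenes == "fail")
      stop("unknown gene column(s): ", paste(extra, collapse = ", "))
    if (length(extra) && unknownGenes == "ignore")
      geneCols <- setdiff(geneCols, extra)
  }
  if (!length(geneCols)) stop("pointcloud file has no gene columns")
  n <- nrow(dat)
  for (cc in c("x", "y", "z", geneCols)) {
    v <- dat[[cc]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("malformed value in column '%s' near data row %d of %s",
                   cc, if (is.na(bad)) 1L else bad, path))
    }
  }
  if (anyDuplicated(dat$id)) stop("duplicated nucleus ids in ", path)
  dat <- dat[order(dat$id), , drop = FALSE]
  idmap <- stats::setNames(seq_len(n), dat$id)
  nb <- rep(list(integer(0)), n)
  if ("neighbors" %in% names(dat)) {
    raw <- as.character(dat$neighbors)
    for (i in seq_len(n)) {
      if (is.na(raw[i]) || raw[i] == "") next
      ids <- strsplit(raw[i], ";", fixed = TRUE)[[1]]
      mapped <- idmap[ids]
      if (anyNA(mapped))
        stop(sprintf("unknown neighbor id in data row %d of %s", i, path))
      nb[[i]] <- as.integer(mapped)
    }
  }
  stage <- if (!is.null(meta$stage)) meta$stage else 0
  Pointcloud(
    coords = as.matrix(dat[, c("x", "y", "z")]),
    expr = as.matrix(dat[, geneCols, drop = FALSE]),
    neighbors = nb,
    species = if (!is.null(meta$species)) meta$species else "unknown",
    stage = stage,
    cohort = if (!is.null(meta$cohort)) as.integer(meta$cohort)
             else cohortFromStage(stage),
    metadata = meta[setdiff(names(meta), c("species", "stage", "cohort"))]
  )
}

.readBdtnp <- function(path) {
  dat <- utils::read.table(path, header = TRUE, comment.char = "#",
                           check.names = FALSE)
  lc <- tolower(names(dat))
  xi <- match(c("x", "y", "z"), lc)
  if (anyNA(xi))
    stop("BDTNP-style file needs x, y, z columns in its header line")
  geneCols <- setdiff(seq_along(dat), c(xi, which(lc == "id")))
  geneCols <- geneCols[vapply(dat[geneCols], is.numeric, TRUE)]
  if (!length(geneCols)) stop("no numeric gene columns found in ", path)
  expr <- as.matrix(dat[, geneCols, drop = FALSE])
  expr[expr < 0] <- 0 # deposited files may contain small negatives
  Pointcloud(coords = as.matrix(dat[, xi]), expr = expr,
             species = "unknown", stage = 0)
}

#' Write a pointcloud file (tabular dialect)
#'
#' Writes coordinates and expression to 6 decimal places; re-reading gives
#' an equal pointcloud at that precision.
#'
#' @param pc a valid [Pointcloud] with at least one gene.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePointcloud <- function(pc, path) {
  stopifnot(is(pc, "Pointcloud"))
  validObject(pc)
  if (ncol(pc@expr) == 0L)
    stop("refusing to write a pointcloud with an empty gene list")
  meta <- list(species = pc@species, stage = pc@stage, cohort = pc@cohort)
  for (k in c("dorsal", "anterior"))
    if (!is.null(pc@metadata[[k]])) meta[[k]] <- pc@metadata[[k]]
  df <- data.frame(id = seq_len(nrow(pc@coords)),
                   x = round(pc@coords[, 1], 6),
                   y = round(pc@coords[, 2], 6),
                   z = round(pc@coords[, 3], 6),
                   check.names = FALSE)
  for (g in colnames(pc@expr)) df[[g]] <- round(pc@expr[, g], 6)
  df$neighbors <- vapply(pc@neighbors, paste, "", collapse = ";")
  .writeMetaCsv(df, meta, path)
  invisible(path)
}

#' Write an atlas directory
#'
#' One CSV per cohort (`cohort<t>.csv` with id, x, y, z and per-gene mean
#' columns, plus `<gene>__sd` columns when the std tensor is present),
#' `correspondence_<t>_<t+1>.csv` files, and `atlas_meta.csv`.
#'
#' @param atlas an [Atlas].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeAtlas <- function(atlas, dir) {
  stopifnot(is(atlas, "Atlas"))
  validObject(atlas)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(species = atlas@species, egg_length = atlas@eggLength)
  for (k in c("dorsal", "anterior"))
    if (!is.null(atlas@metadata[[k]])) meta[[k]] <- atlas@metadata[[k]]
  for (t in seq_along(atlas@positions)) {
    p <- atlas@positions[[t]]
    df <- data.frame(id = seq_len(nrow(p)), x = round(p[, 1], 6),
                     y = round(p[, 2], 6), z = round(p[, 3], 6))
    for (g in atlas@genes) df[[g]] <- round(atlas@E[[t]][, g], 6)
    if (length(atlas@S))
      for (g in atlas@genes)
        df[[paste0(g, "__sd")]] <- round(atlas@S[[t]][, g], 6)
    .writeMetaCsv(df, c(meta, list(cohort = t)),
                  file.path(dir, sprintf("cohort%d.csv", t)))
  }
  for (t in seq_along(atlas@correspondence)) {
    m <- atlas@correspondence[[t]]
    utils::write.csv(
      data.frame(from = seq_along(m), to = m),
      file.path(dir, sprintf("correspondence_%d_%d.csv", t, t + 1)),
      row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read an atlas directory written by [writeAtlas()]
#'
#' @param dir atlas directory.
#' @return an [Atlas].
#' @export
readAtlas <- function(dir) {
  files <- file.path(dir, sprintf("cohort%d.csv", 1:6))
  if (!all(file.exists(files)))
    stop("atlas directory must contain cohort1.csv .. cohort6.csv")
  positions <- vector("list", 6L); E <- vector("list", 6L)
  S <- vector("list", 6L)
  genesRef <- NULL; meta <- NULL; hasSd <- FALSE
  for (t in 1:6) {
    md <- .readMetaCsv(files[t])
    dat <- md$data
    if (t == 1L) meta <- md$meta
    cols <- setdiff(names(dat), c("id", "x", "y", "z"))
    sdCols <- grep("__sd$", cols, value = TRUE)
    gcols <- setdiff(cols, sdCols)
    if (is.null(genesRef)) genesRef <- gcols
    positions[[t]] <- as.matrix(dat[, c("x", "y", "z")])
    E[[t]] <- as.matrix(dat[, genesRef, drop = FALSE])
    if (length(sdCols)) {
      hasSd <- TRUE
      S[[t]] <- as.matrix(dat[, paste0(genesRef, "__sd"), drop = FALSE])
      colnames(S[[t]]) <- genesRef
    }
  }
  corr <- vector("list", 5L)
  for (t in 1:5) {
    f <- file.path(dir, sprintf("correspondence_%d_%d.csv", t, t + 1))
    corr[[t]] <- if (file.exists(f))
      as.integer(utils::read.csv(f)$to) else seq_len(nrow(positions[[t]]))
  }
  new("Atlas",
      species = if (!is.null(meta$species)) meta$species else "unknown",
      genes = genesRef, positions = positions, E = E,
      S = if (hasSd) S else list(), correspondence = corr,
      eggLength = if (!is.null(meta$egg_length)) meta$egg_length
                  else max(positions[[6]][, 1]) - min(positions[[6]][, 1]),
      metadata = meta[setdiff(names(meta),
                              c("species", "egg_length", "cohort"))])
}
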
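## End-to-end orchestration: synth -> build -> morph -> celltypes -> dist
## -> timewarp, with a JSON run summary recording all resolved parameters
## and the seed. A thin command-line wrapper around these functions ships
## in inst/scripts/flyatlas.R.

#' Build a pipeline configuration
#'
#' Resolves all tunable parameters of the demo pipeline. Values loaded
#' from an optional YAML/JSON config file are overridden by arguments
#' supplied here (explicit arguments win).
#'
#' @param outDir output directory (required; created by [runPipeline()]).
#' @param nSpecies,nNuclei,seed synthetic generator controls; `nNuclei`
#'   is recycled per species.
#' @param nEmbryos embryos per cohort for atlas building.
#' @param k,m,minFrac,grid analysis parameters (candidate neighborhood,
#'   displacement averaging, rare-type filter, density grid dims).
#' @param refSpecies index of the reference species (default 1).
#' @param stages character subset of
#'   `c("synth", "build", "morph", "celltypes", "dist", "timewarp")`.
#' @param configFile optional YAML (or JSON) file of defaults.
#' @param verbose logical; log progress to stderr.
#' @return a named list of resolved parameters (class `flyatlasConfig`).
#' @export
runConfig <- function(outDir, nSpecies = 3L, nNuclei = 1000L,
                      nEmbryos = 4L, k = 30L, m = 10L, minFrac = 0.001,
                      grid = c(50L, 16L), refSpecies = 1L,
                      stages = c("synth", "build", "morph", "celltypes",
                                 "dist", "timewarp"),
                      seed = 1L, configFile = NULL, verbose = TRUE) {
  cfg <- list()
  if (!is.null(configFile)) {
    if (!file.exists(configFile)) stop("config file not found: ", configFile)
    cfg <- if (grepl("\\.json$", configFile)) {
      jsonlite::read_json(configFile, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package")
      yaml::read_yaml(configFile)
    }
  }
  supplied <- as.list(environment())[c("outDir", "nSpecies", "nNuclei",
    "nEmbryos", "k", "m", "minFrac", "grid", "refSpecies", "stages",
    "seed", "verbose")]
  given <- names(as.list(match.call()))[-1]
  out <- supplied
  for (nm in names(out))
    if (!nm %in% given && !is.null(cfg[[nm]])) out[[nm]] <- cfg[[nm]]
  out$nSpecies <- as.integer(out$nSpecies)
  out$nNuclei <- rep_len(as.integer(out$nNuclei), out$nSpecies)
  out$seed <- as.integer(out$seed)
  stopifnot(out$nSpecies >= 1L, all(out$stages %in%
    c("synth", "build", "morph", "celltypes", "dist", "timewarp")))
  class(out) <- "flyatlasConfig"
  out
}

.log <- function(verbose, ...) {
  if (verbose)
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), sprintf(...))
}

#' Run the demo analysis pipeline
#'
#' Generates synthetic species atlases, rebuilds one species' atlas from
#' noisy embryos, computes morphology tables and density maps, runs the
#' binary cell-type analysis, expression distance scores against the
#' reference species, and the developmental time matching, writing
#' TSV/CSV artifacts plus `run_summary.json` (all resolved parameters and
#' the seed) under `config$outDir`. Inputs are never mutated; all outputs
#' stay under the output directory. Deterministic given the seed.
#'
#' @param config a configuration from [runConfig()].
#' @return invisibly, a named list of written artifact paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "flyatlasConfig"))
  v <- isTRUE(config$verbose)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  spec <- syntheticSpec(nSpecies = config$nSpecies,
                        nNuclei = config$nNuclei, seed = config$seed)
  .log(v, "generating %d synthetic species atlases", config$nSpecies)
  gen <- lapply(seq_len(config$nSpecies), function(s)
    generateAtlas(spec, s))
  atlases <- lapply(gen, `[[`, "atlas")
  if ("synth" %in% config$stages) {
    for (a in atlases) {
      d <- file.path(config$outDir, "atlases", a@species)
      writeAtlas(a, d)
      paths[[paste0("atlas_", a@species)]] <- d
    }
    truthFile <- file.path(config$outDir, "ground_truth.json")
    jsonlite::write_json(
      list(seed = config$seed,
           species = spec@speciesNames[seq_len(config$nSpecies)],
           shiftField = spec@shiftField[seq_len(config$nSpecies)],
           temporalOffset = spec@temporalOffset[seq_len(config$nSpecies)]),
      truthFile, auto_unbox = TRUE, digits = NA)
    paths$ground_truth <- truthFile
  }
  if ("build" %in% config$stages) {
    .log(v, "rebuilding species 1 atlas from %d embryos/cohort",
         config$nEmbryos)
    sets <- lapply(1:6, function(t)
      generateEmbryoSet(spec, config$nEmbryos, t, 1L,
                        atlas = gen[[1]])$embryos)
    rebuilt <- buildAtlas(sets)
    d <- file.path(config$outDir, "rebuilt_atlas")
    writeAtlas(rebuilt, d)
    paths$rebuilt_atlas <- d
    q <- expressionQuality(rebuilt)
    qt <- data.frame(gene = rownames(q$byCohort), q$byCohort,
                     mean = q$perGene, check.names = FALSE)
    f <- file.path(config$outDir, "quality.tsv")
    utils::write.table(qt, f, sep = "\t", row.names = FALSE, quote = FALSE)
    paths$quality <- f
  }
  if ("morph" %in% config$stages) {
    .log(v, "morphology tables")
    morph <- do.call(rbind, lapply(seq_along(atlases), function(s) {
      pc <- atlasPointcloud(gen[[s]], 6L)
      data.frame(species = atlases[[s]]@species,
                 nNuclei = nNuclei(pc),
                 eggLength = eggLength(pc),
                 surfaceArea = surfaceArea(pc),
                 meanDensity = mean(localDensity(pc)))
    }))
    f <- file.path(config$outDir, "morphology.tsv")
    utils::write.table(morph, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths$morphology <- f
    emb <- generateEmbryoSet(spec, 1L, 6L, 1L, atlas = gen[[1]])$embryos
    dm <- densityMap(emb, 6L, grid = config$grid)
    f <- file.path(config$outDir, "density_map_cohort6.tsv")
    utils::write.table(densityMapTable(dm), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths$density_map <- f
  }
  profiles <- NULL
  if (any(c("celltypes", "timewarp") %in% config$stages)) {
    .log(v, "binary cell-type analysis")
    callsList <- lapply(atlases, binarize)
    profiles <- enumerateCellTypes(callsList, minFrac = config$minFrac)
    if ("celltypes" %in% config$stages) {
      d <- file.path(config$outDir, "celltypes")
      dir.create(d, showWarnings = FALSE)
      summ <- cellTypeSummary(profiles)
      utils::write.table(summ, file.path(d, "summary.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      for (p in profiles) {
        tab <- data.frame(type = p@types, p@proportions,
                          check.names = FALSE)
        utils::write.table(tab,
          file.path(d, sprintf("proportions_%s.tsv", p@species)),
          sep = "\t", row.names = FALSE, quote = FALSE)
      }
      gcd <- geneCountDistribution(callsList[[config$refSpecies]])
      utils::write.table(data.frame(nGenes = rownames(gcd), gcd,
                                    check.names = FALSE),
                         file.path(d, "gene_counts.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      paths$celltypes <- d
    }
  }
  if ("dist" %in% config$stages && config$nSpecies >= 2L) {
    .log(v, "expression distance scores vs species %d", config$refSpecies)
    d <- file.path(config$outDir, "dist")
    dir.create(d, showWarnings = FALSE)
    refN <- normalizeExpression(atlases[[config$refSpecies]])
    for (s in setdiff(seq_len(config$nSpecies), config$refSpecies)) {
      res <- localBestMatch(refN, normalizeExpression(atlases[[s]]),
                            k = config$k, m = config$m)
      tb <- matchTable(res)
      utils::write.table(tb,
        file.path(d, sprintf("match_%s_%s.tsv", res@refSpecies,
                             res@targetSpecies)),
        sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(ref = res@refSpecies, target = res@targetSpecies,
             median_spatial_D = stats::median(tb$spatial_dist),
             median_local_best_D = stats::median(tb$local_best_dist),
             mean_spatial_D = mean(tb$spatial_dist),
             mean_local_best_D = mean(tb$local_best_dist)),
        file.path(d, sprintf("summary_%s_%s.json", res@refSpecies,
                             res@targetSpecies)),
        auto_unbox = TRUE, digits = NA)
    }
    paths$dist <- d
  }
  if ("timewarp" %in% config$stages && config$nSpecies >= 2L) {
    .log(v, "time-point matching")
    d <- file.path(config$outDir, "timewarp")
    dir.create(d, showWarnings = FALSE)
    pathsList <- list()
    for (s in setdiff(seq_len(config$nSpecies), config$refSpecies)) {
      tm <- matchTimepoints(profileDistanceMatrix(
        profiles[[config$refSpecies]], profiles[[s]]))
      utils::write.table(distMatrix(tm),
        file.path(d, sprintf("distmatrix_%s.tsv",
                             profiles[[s]]@species)),
        sep = "\t", row.names = FALSE, quote = FALSE)
      pathsList[[profiles[[s]]@species]] <- warpPath(tm)
    }
    jsonlite::write_json(pathsList, file.path(d, "paths.json"),
                         digits = NA)
    if (config$nSpecies >= 2L) {
      hc <- hourglassCurve(profiles)
      utils::write.table(hc, file.path(d, "hourglass.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    paths$timewarp <- d
  }
  summary <- config
  class(summary) <- NULL
  summary$package_version <- as.character(utils::packageVersion("flyatlas"))
  f <- file.path(config$outDir, "run_summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA)
  paths$run_summary <- f
  .log(v, "done: %d artifacts under %s", length(paths), config$outDir)
  invisible(paths)
}
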
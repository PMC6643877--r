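#' SyntheticSpec: parameters of the synthetic atlas generator
#'
#' Describes a family of synthetic "species": embryo geometry (ellipsoid of
#' revolution), nucleus counts, an AP-patterned gene panel (gap-like logistic
#' domains, pair-rule-like 7-stripe patterns, terminal-like domains),
#' per-cohort sharpening dynamics, species-level AP domain shifts and
#' temporal offsets with recorded ground truth, per-embryo gain/offset noise,
#' and low-density furrow regions.
#'
#' @slot speciesNames character vector.
#' @slot eggLength numeric per species (um).
#' @slot maxRadius numeric per species (um), equatorial radius.
#' @slot nNuclei integer per species, target nucleus count.
#' @slot genes character vector of gene names.
#' @slot geneRoles character per gene: "gap", "terminal" or "pairrule".
#' @slot domains list per gene. For gap/terminal genes: a list of domains,
#'   each `list(lo, hi, width, amp)` with boundaries as fractions of egg
#'   length in [0, 1] (`lo = 0` / `hi = 1` denote open edges); for pair-rule
#'   genes: `list(centers, sigma, amp)` with 7 stripe centers.
#' @slot shiftField numeric per species: AP displacement (fraction of egg
#'   length) applied to all domains relative to the reference species.
#' @slot temporalOffset integer per species: shift of the dynamic program in
#'   cohort units (positive = development lags the morphological clock).
#' @slot widthFactor numeric(6): per-cohort multiplier on boundary widths
#'   and stripe sigmas (decreasing = sharpening).
#' @slot ampFactor list with numeric(6) entries `gap`, `terminal`,
#'   `pairrule`: per-cohort amplitude multipliers.
#' @slot noise list: `gainSdLog` (sd of log per-embryo multiplicative gain),
#'   `offsetRange` (length-2, uniform positive background offset),
#'   `nucleusSd` (per-nucleus additive noise sd as a fraction of each
#'   gene's maximum level).
#' @slot furrows list of low-density regions, each
#'   `list(ap, phi, depth, sigmaAp, sigmaPhi)` (`phi = NA` for a ring
#'   depression spanning all angles).
#' @slot seed integer(1); all generator randomness derives from it.
#' @seealso [syntheticSpec()], [generateAtlas()], [generateEmbryoSet()]
#' @export
setClass("SyntheticSpec",
  representation(
    speciesNames = "character", eggLength = "numeric",
    maxRadius = "numeric", nNuclei = "integer",
    genes = "character", geneRoles = "character", domains = "list",
    shiftField = "numeric", temporalOffset = "integer",
    widthFactor = "numeric", ampFactor = "list",
    noise = "list", furrows = "list", seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  ns <- length(object@speciesNames)
  for (sl in c("eggLength", "maxRadius", "nNuclei", "shiftField",
               "temporalOffset"))
    if (length(slot(object, sl)) != ns)
      msg <- c(msg, sprintf("%s must have one entry per species", sl))
  if (any(object@eggLength <= 0) || any(object@maxRadius <= 0))
    msg <- c(msg, "egg lengths and radii must be positive")
  if (any(object@nNuclei < 10L))
    msg <- c(msg, "at least 10 nuclei per species required")
  ng <- length(object@genes)
  if (length(object@geneRoles) != ng || length(object@domains) != ng)
    msg <- c(msg, "geneRoles and domains must have one entry per gene")
  if (!all(object@geneRoles %in% c("gap", "terminal", "pairrule")))
    msg <- c(msg, "geneRoles must be gap, terminal or pairrule")
  for (g in seq_len(ng)) {
    d <- object@domains[[g]]
    if (object@geneRoles[g] == "pairrule") {
      if (d$sigma <= 0 || d$amp < 0 ||
          any(d$centers < 0) || any(d$centers > 1))
        msg <- c(msg, sprintf("gene %s: invalid stripe parameters",
                              object@genes[g]))
    } else {
      for (dom in d) {
        if (dom$width <= 0 || dom$amp < 0 || dom$lo < 0 || dom$hi > 1 ||
            dom$lo >= dom$hi)
          msg <- c(msg, sprintf("gene %s: invalid domain parameters",
                                object@genes[g]))
      }
    }
  }
  if (length(object@widthFactor) != 6L || any(object@widthFactor <= 0))
    msg <- c(msg, "widthFactor must be 6 positive values")
  for (role in c("gap", "terminal", "pairrule"))
    if (length(object@ampFactor[[role]]) != 6L ||
        any(object@ampFactor[[role]] < 0))
      msg <- c(msg, sprintf("ampFactor$%s must be 6 non-negative values", role))
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d species, %d genes, seed %d\n",
              length(object@speciesNames), length(object@genes),
              object@seed))
  cat(sprintf("  species: %s\n",
              paste(object@speciesNames, collapse = ", ")))
  cat(sprintf("  egg lengths (um): %s; nuclei: %s\n",
              paste(object@eggLength, collapse = ", "),
              paste(object@nNuclei, collapse = ", ")))
  cat(sprintf("  AP shifts (EL): %s; temporal offsets: %s\n",
              paste(object@shiftField, collapse = ", "),
              paste(object@temporalOffset, collapse = ", ")))
})

#' Default 9-gene synthetic panel
#'
#' Gap-like domains, terminal-like domains and 7-stripe pair-rule-like
#' patterns loosely arranged like the blastoderm AP panel (hb, gt, Kr, kni,
#' tll, hkb, eve, ftz, odd). Boundaries are fractions of egg length.
#' @return list with `genes`, `roles` and `domains`.
#' @keywords internal
.defaultPanel <- function() {
  dom <- function(lo, hi, width, amp) list(lo = lo, hi = hi,
                                           width = width, amp = amp)
  stripes7 <- function(offset, sigma = 0.015, amp = 1)
    list(centers = seq(0.30, 0.78, length.out = 7) + offset,
         sigma = sigma, amp = amp)
  list(
    genes = c("hb", "gt", "Kr", "kni", "tll", "hkb", "eve", "ftz", "odd"),
    roles = c("gap", "gap", "gap", "gap", "terminal", "terminal",
              "pairrule", "pairrule", "pairrule"),
    domains = list(
      hb  = list(dom(0, 0.47, 0.020, 1.0), dom(0.78, 0.92, 0.020, 0.7)),
      gt  = list(dom(0.08, 0.28, 0.020, 0.9), dom(0.72, 0.85, 0.020, 0.9)),
      Kr  = list(dom(0.43, 0.58, 0.020, 1.0)),
      kni = list(dom(0.60, 0.72, 0.020, 0.9)),
      tll = list(dom(0, 0.06, 0.015, 0.5), dom(0.84, 1, 0.015, 1.0)),
      hkb = list(dom(0, 0.04, 0.012, 0.9), dom(0.93, 1, 0.012, 0.9)),
      eve = stripes7(0),
      ftz = stripes7(0.027),
      odd = stripes7(0.040)
    )
  )
}

#' Build a synthetic-atlas specification
#'
#' Defaults describe the five-species study conditions: egg lengths and
#' nucleus counts matching the five measured Drosophilid species
#' (melanogaster-, simulans-, yakuba-, pseudoobscura- and virilis-like),
#' a 9-gene AP panel, per-cohort sharpening over the six blastoderm time
#' cohorts, small AP domain shifts and temporal offsets growing with
#' phylogenetic-like distance from the first (reference) species, lognormal
#' per-embryo gains with positive background offsets, and cephalic/ventral
#' furrow density depressions.
#'
#' @param nSpecies number of species to keep (first `nSpecies` defaults).
#' @param speciesNames,eggLength,maxRadius,nNuclei per-species parameters.
#' @param genes,geneRoles,domains gene panel (see [SyntheticSpec-class]).
#' @param shiftField AP shift per species (fraction of egg length).
#' @param temporalOffset integer cohort shift per species.
#' @param widthFactor,ampFactor per-cohort dynamics.
#' @param noise list(gainSdLog, offsetRange, nucleusSd).
#' @param furrows list of density depressions.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated `SyntheticSpec`.
#' @examples
#' spec <- syntheticSpec(nSpecies = 2, nNuclei = c(800, 800), seed = 7)
#' spec
#' @export
syntheticSpec <- function(nSpecies = 5L,
                          speciesNames = c("mel", "sim", "yak", "pse",
                                           "vir")[seq_len(nSpecies)],
                          eggLength = c(393.8, 416.2, 450.9, 394.1,
                                        457.4)[seq_len(nSpecies)],
                          maxRadius = eggLength / 5,
                          nNuclei = c(5974L, 5894L, 6115L, 5081L,
                                      5535L)[seq_len(nSpecies)],
                          genes = NULL, geneRoles = NULL, domains = NULL,
                          shiftField = c(0, 0.005, 0.01, 0.02,
                                         0.03)[seq_len(nSpecies)],
                          temporalOffset = c(0L, 0L, 1L, 1L,
                                             2L)[seq_len(nSpecies)],
                          widthFactor = c(1.7, 1.45, 1.25, 1.05, 0.9, 0.75),
                          ampFactor = list(
                            gap = c(0.7, 0.85, 1, 1, 1, 0.95),
                            terminal = c(0.8, 0.9, 1, 1, 1, 0.9),
                            pairrule = c(0.25, 0.45, 0.7, 0.9, 1, 1)),
                          noise = list(gainSdLog = 0.2,
                                       offsetRange = c(0.01, 0.05),
                                       nucleusSd = 0.02),
                          furrows = list(
                            list(ap = 0.32, phi = NA, depth = 0.5,
                                 sigmaAp = 0.03, sigmaPhi = NA),
                            list(ap = 0.5, phi = pi, depth = 0.45,
                                 sigmaAp = 0.25, sigmaPhi = 0.5)),
                          seed = 1L) {
  if (is.null(genes)) {
    panel <- .defaultPanel()
    genes <- panel$genes; geneRoles <- panel$roles; domains <- panel$domains
  }
  new("SyntheticSpec",
      speciesNames = speciesNames, eggLength = as.numeric(eggLength),
      maxRadius = as.numeric(maxRadius), nNuclei = as.integer(nNuclei),
      genes = genes, geneRoles = geneRoles, domains = domains,
      shiftField = as.numeric(shiftField),
      temporalOffset = as.integer(temporalOffset),
      widthFactor = widthFactor, ampFactor = ampFactor,
      noise = noise, furrows = furrows, seed = as.integer(seed))
}
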
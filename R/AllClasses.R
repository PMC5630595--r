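#' @import methods
NULL

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' SyntheticConfig: parameters for the synthetic study generator
#'
#' Bundles every tunable of the synthetic cohort/proteome/variant/screen
#' generator. Defaults emulate a 1000 Genomes-scale diploid cohort mapped
#' onto protein families: 2,504 individuals in five super-populations, a
#' per-haplotype per-residue missense rate of 4e-4 (roughly 23M alleles over
#' 11M aa and 5,008 haplotypes), one planted strongly-enriched conserved
#' column standing in for the GPCR DRY arginine, per-gene loss-of-function
#' rates, and a receptor/odorant screen with canonical and non-canonical
#' positive rates matching the published OR screen contingency.
#'
#' @slot nIndividuals number of diploid individuals.
#' @slot subpopWeights named numeric vector of sub-population weights
#'   (must sum to 1).
#' @slot nFamilies number of protein families.
#' @slot membersPerFamily integer length-2 range (min, max) of members.
#' @slot modelLength integer length-2 range of family model lengths.
#' @slot baseVariantRate per-allele (haplotype) per-residue missense
#'   probability.
#' @slot plantedPositions data.frame with columns family (index), column,
#'   multiplier (>= 1); rows mark columns whose variant rate is multiplied.
#' @slot lofRates named numeric: per-gene per-haplotype probabilities for
#'   \code{stop_gain} and \code{frameshift}.
#' @slot screen list: nReceptors, nOdorants, canonicalRate,
#'   nonCanonicalRate, ec50Range (log10 molar, within [-9, 0]),
#'   nonCanonicalFraction of receptors.
#' @slot conservedPerFamily number of columns per family built conserved.
#' @slot consHigh,consLow probability a member carries the consensus
#'   residue at conserved / ordinary columns.
#' @slot gapRate per-member per-column probability of a deletion (gap).
#' @slot insRate per-member per-column probability of an insertion after
#'   the column.
#' @slot flankMax maximal random flank length either side of the domain.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    nIndividuals = "integer",
    subpopWeights = "numeric",
    nFamilies = "integer",
    membersPerFamily = "integer",
    modelLength = "integer",
    baseVariantRate = "numeric",
    plantedPositions = "data.frame",
    lofRates = "numeric",
    screen = "list",
    conservedPerFamily = "integer",
    consHigh = "numeric",
    consLow = "numeric",
    gapRate = "numeric",
    insRate = "numeric",
    flankMax = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (abs(sum(object@subpopWeights) - 1) > 1e-9)
    msg <- c(msg, "subpopWeights must sum to 1 (within 1e-9)")
  if (any(object@subpopWeights < 0)) msg <- c(msg, "negative subpop weight")
  if (is.null(names(object@subpopWeights)))
    msg <- c(msg, "subpopWeights must be named")
  if (object@nFamilies < 1L) msg <- c(msg, "nFamilies must be >= 1")
  for (fld in c("membersPerFamily", "modelLength")) {
    v <- slot(object, fld)
    if (length(v) != 2L || any(v < 1L) || v[1] > v[2])
      msg <- c(msg, paste0(fld, " must be an increasing length-2 range >= 1"))
  }
  if (object@baseVariantRate < 0 || object@baseVariantRate > 1)
    msg <- c(msg, "baseVariantRate must be in [0, 1]")
  pp <- object@plantedPositions
  if (nrow(pp) &&
      (!all(c("family", "column", "multiplier") %in% names(pp)) ||
       any(pp$multiplier < 1)))
    msg <- c(msg, "plantedPositions needs family/column/multiplier >= 1")
  if (!all(c("stop_gain", "frameshift") %in% names(object@lofRates)) ||
      any(object@lofRates < 0) || any(object@lofRates > 1))
    msg <- c(msg, "lofRates must name stop_gain and frameshift in [0, 1]")
  sc <- object@screen
  need <- c("nReceptors", "nOdorants", "canonicalRate", "nonCanonicalRate",
            "ec50Range", "nonCanonicalFraction")
  if (!all(need %in% names(sc))) {
    msg <- c(msg, paste("screen config needs:", paste(need, collapse = ", ")))
  } else if (any(sc$ec50Range < -9) || any(sc$ec50Range > 0) ||
             sc$ec50Range[1] > sc$ec50Range[2]) {
    msg <- c(msg, "screen ec50Range must be an increasing range within [-9, 0]")
  }
  if (length(msg)) msg else TRUE
})

#' FamilyAlignment: one protein family with residue-to-column mappings
#'
#' Represents a profile-style family alignment: a model of fixed length,
#' member proteins each contributing one domain instance with a partial,
#' strictly increasing residue-to-column map (gap = residue column NA is not
#' stored; insertions are residues with no column), the aligned residues as
#' a members x columns character matrix, and a per-column consensus table.
#'
#' @slot family family identifier.
#' @slot modelLength number of alignment (match) columns.
#' @slot members data.frame: protein, start, end (1-based inclusive domain
#'   bounds on the protein).
#' @slot columnMaps list (one per member, named by protein) of integer
#'   vectors of length end-start+1: element i is the column of residue
#'   start+i-1, or NA for an insertion residue.
#' @slot residueMatrix character matrix (members x modelLength): residue at
#'   each column, NA where the member has a gap.
#' @slot consensus data.frame: column, residue, frequency, nAligned,
#'   conserved. May be empty until \code{computeConsensus} is called.
#' @exportClass FamilyAlignment
setClass("FamilyAlignment",
  representation(
    family = "character",
    modelLength = "integer",
    members = "data.frame",
    columnMaps = "list",
    residueMatrix = "matrix",
    consensus = "data.frame"
  )
)

setValidity("FamilyAlignment", function(object) {
  msg <- character()
  m <- object@members
  if (!all(c("protein", "start", "end") %in% names(m)))
    return("members needs protein/start/end")
  if (any(m$start > m$end)) msg <- c(msg, "start must be <= end")
  if (length(object@columnMaps) != nrow(m))
    msg <- c(msg, "one columnMap per member required")
  for (i in seq_len(nrow(m))) {
    cm <- object@columnMaps[[i]]
    if (length(cm) != m$end[i] - m$start[i] + 1L) {
      msg <- c(msg, sprintf("columnMap %d length mismatch", i))
      next
    }
    v <- cm[!is.na(cm)]
    if (length(v)) {
      if (any(v < 1L) || any(v > object@modelLength))
        msg <- c(msg, sprintf("columnMap %d outside [1, modelLength]", i))
      if (any(diff(v) <= 0L))
        msg <- c(msg, sprintf("columnMap %d not strictly increasing", i))
    }
  }
  if (!identical(dim(object@residueMatrix),
                 c(nrow(m), as.integer(object@modelLength))))
    msg <- c(msg, "residueMatrix must be members x modelLength")
  if (length(msg)) msg else TRUE
})

#' Proteome: family alignments plus protein and coding sequences
#'
#' @slot alignments list of \linkS4class{FamilyAlignment}, named by family.
#' @slot proteins \link[Biostrings]{AAStringSet} of full protein sequences.
#' @slot cds \link[Biostrings]{DNAStringSet} of coding sequences (no stop
#'   codon); translation equals the protein sequence.
#' @exportClass Proteome
setClass("Proteome",
  representation(
    alignments = "list",
    proteins = "ANY",
    cds = "ANY"
  )
)

setValidity("Proteome", function(object) {
  msg <- character()
  if (!methods::is(object@proteins, "AAStringSet"))
    msg <- c(msg, "proteins must be an AAStringSet")
  if (!methods::is(object@cds, "DNAStringSet"))
    msg <- c(msg, "cds must be a DNAStringSet")
  if (!all(vapply(object@alignments, inherits, TRUE, "FamilyAlignment")))
    msg <- c(msg, "alignments must all be FamilyAlignment")
  if (length(msg)) msg else TRUE
})

#' VariantSet: per-individual diploid protein variants
#'
#' A variant table (one row per unique protein change) with a matching
#' genotype matrix of per-individual alternate-allele counts in {0, 1, 2},
#' and the cohort table the columns refer to.
#'
#' @slot variants data.frame: protein, position (1-based residue), ref,
#'   alt (residue letter for missense, "*" for stop_gain, "fs" for
#'   frameshift), consequence in {missense, stop_gain, frameshift}.
#' @slot geno integer matrix, variants x individuals, values in {0, 1, 2};
#'   colnames are individual ids.
#' @slot cohort data.frame: id, subpop, sex.
#' @exportClass VariantSet
setClass("VariantSet",
  representation(
    variants = "data.frame",
    geno = "matrix",
    cohort = "data.frame"
  )
)

setValidity("VariantSet", function(object) {
  msg <- character()
  v <- object@variants
  need <- c("protein", "position", "ref", "alt", "consequence")
  if (!all(need %in% names(v)))
    return(paste("variants needs:", paste(need, collapse = ", ")))
  if (nrow(v) != nrow(object@geno))
    msg <- c(msg, "geno must have one row per variant")
  if (nrow(object@cohort) != ncol(object@geno))
    msg <- c(msg, "geno must have one column per individual")
  if (!identical(as.character(object@cohort$id), colnames(object@geno)))
    msg <- c(msg, "geno colnames must match cohort ids")
  if (nrow(v)) {
    if (any(v$position < 1L)) msg <- c(msg, "positions must be >= 1")
    bad <- !(v$consequence %in% c("missense", "stop_gain", "frameshift"))
    if (any(bad)) msg <- c(msg, "unknown consequence class")
    mis <- v$consequence == "missense"
    if (any(mis & v$ref == v$alt))
      msg <- c(msg, "missense ref and alt must differ")
    g <- object@geno
    if (length(g) && (any(g < 0L, na.rm = TRUE) ||
                      any(g > 2L, na.rm = TRUE)))
      msg <- c(msg, "allele counts must be in {0, 1, 2}")
  }
  if (length(msg)) msg else TRUE
})

#' OdorScreen: receptor/odorant screening results
#'
#' @slot table data.frame: receptor, odorant, log10Ec50 (log10 molar EC50
#'   in [-9, 0] for positives, NA for negative screens).
#' @slot canonical optional named logical: ground-truth canonical status
#'   per receptor (filled by the synthetic generator, empty otherwise).
#' @exportClass OdorScreen
setClass("OdorScreen",
  representation(
    table = "data.frame",
    canonical = "logical"
  )
)

setValidity("OdorScreen", function(object) {
  tb <- object@table
  if (!all(c("receptor", "odorant", "log10Ec50") %in% names(tb)))
    return("table needs receptor/odorant/log10Ec50")
  v <- tb$log10Ec50[!is.na(tb$log10Ec50)]
  if (length(v) && (any(v > 0) || any(v < -9)))
    return("log10Ec50 must lie in [-9, 0]")
  TRUE
})

#' OdorWorld: state of the odorant-driven agent-based simulation
#'
#' Grid world with point odorant sources and diploid genotyped animals.
#' Animals carry two alleles of each receptor gene; an allele is a sparse
#' attraction/repulsion profile over odorants (+1 attract, -1 repel, 0 no
#' response). The per-animal response to an odorant sums, over genes, the
#' sign of the two alleles' responses (heterozygous conflicts cancel).
#'
#' @slot gridDim integer length-2 grid dimensions.
#' @slot odorants integer matrix (sources x 2) of grid coordinates.
#' @slot params list of simulation parameters; its \code{env} element is
#'   the environment holding the mutable state (positions, sexes,
#'   genotypes, allele pool, responses, occupancy, births), which
#'   \code{worldStep} updates by reference.
#' @slot step integer step counter (mirrors the state environment).
#' @exportClass OdorWorld
setClass("OdorWorld",
  representation(
    gridDim = "integer",
    odorants = "matrix",
    params = "list",
    step = "integer"
  )
)

setValidity("OdorWorld", function(object) {
  msg <- character()
  if (nrow(object@odorants)) {
    o <- object@odorants
    if (any(o[, 1] < 1L) || any(o[, 1] > object@gridDim[1]) ||
        any(o[, 2] < 1L) || any(o[, 2] > object@gridDim[2]))
      msg <- c(msg, "odorant positions out of bounds")
  }
  if (!is.environment(object@params$env))
    msg <- c(msg, "params$env must be the state environment")
  if (length(msg)) msg else TRUE
})
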
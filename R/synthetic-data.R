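#' @include AllClasses.R
NULL

#' Build a synthetic study configuration
#'
#' Constructor for \linkS4class{SyntheticConfig}. Defaults describe the
#' emulated study: a 2,504-individual diploid cohort split into the five
#' 1000 Genomes super-populations, 20 protein families of 8-12 members with
#' 80-120 alignment columns, a per-haplotype per-residue missense rate of
#' 4e-4, one conserved column in family 1 with a 10x planted variant rate
#' (a DRY-arginine-like hotspot), per-gene stop-gain/frameshift rates of
#' 0.005 per haplotype, and a receptor/odorant screen whose canonical and
#' non-canonical positive rates are 102/8815 and 1/1089.
#'
#' @param nIndividuals cohort size.
#' @param subpopWeights named weights summing to 1.
#' @param nFamilies,membersPerFamily,modelLength family layout; ranges are
#'   length-2 integer vectors (min, max).
#' @param baseVariantRate per-haplotype per-residue missense probability.
#' @param plantedPositions data.frame (family, column, multiplier) or NULL
#'   for the default single 10x hotspot; use a 0-row data.frame for none.
#' @param lofRates named numeric with stop_gain and frameshift per-gene
#'   per-haplotype probabilities.
#' @param screen list overriding any of nReceptors, nOdorants,
#'   canonicalRate, nonCanonicalRate, ec50Range, nonCanonicalFraction.
#' @param conservedPerFamily,consHigh,consLow,gapRate,insRate,flankMax
#'   alignment texture parameters (see \linkS4class{SyntheticConfig}).
#' @param seed integer RNG seed.
#' @return a validated \linkS4class{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(nIndividuals = 100, nFamilies = 3, seed = 7)
#' cfg
#' @export
syntheticConfig <- function(nIndividuals = 2504L,
                            subpopWeights = c(AFR = 0.26, EUR = 0.20,
                                              EAS = 0.20, SAS = 0.20,
                                              AMR = 0.14),
                            nFamilies = 20L,
                            membersPerFamily = c(8L, 12L),
                            modelLength = c(80L, 120L),
                            baseVariantRate = 4e-4,
                            plantedPositions = NULL,
                            lofRates = c(stop_gain = 0.005,
                                         frameshift = 0.005),
                            screen = list(),
                            conservedPerFamily = 4L,
                            consHigh = 0.95,
                            consLow = 0.40,
                            gapRate = 0.03,
                            insRate = 0.02,
                            flankMax = 10L,
                            seed = 1L) {
  if (is.null(plantedPositions))
    plantedPositions <- data.frame(family = 1L, column = 10L,
                                   multiplier = 10)
  screenDefaults <- list(nReceptors = 60L, nOdorants = 40L,
                         canonicalRate = 102 / 8815,
                         nonCanonicalRate = 1 / 1089,
                         ec50Range = c(-9, -3),
                         nonCanonicalFraction = 0.2)
  screenDefaults[names(screen)] <- screen
  if (length(membersPerFamily) == 1L)
    membersPerFamily <- rep(membersPerFamily, 2L)
  if (length(modelLength) == 1L) modelLength <- rep(modelLength, 2L)
  methods::new("SyntheticConfig",
    nIndividuals = as.integer(nIndividuals),
    subpopWeights = subpopWeights,
    nFamilies = as.integer(nFamilies),
    membersPerFamily = as.integer(membersPerFamily),
    modelLength = as.integer(modelLength),
    baseVariantRate = baseVariantRate,
    plantedPositions = plantedPositions,
    lofRates = lofRates,
    screen = screenDefaults,
    conservedPerFamily = as.integer(conservedPerFamily),
    consHigh = consHigh, consLow = consLow,
    gapRate = gapRate, insRate = insRate,
    flankMax = as.integer(flankMax),
    seed = as.integer(seed))
}

#' Generate a synthetic diploid cohort
#'
#' Draws sub-population labels by the configured weights and assigns ids
#' and sexes. Deterministic for a fixed config seed.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return data.frame with columns id, subpop, sex.
#' @examples
#' coh <- generateCohort(syntheticConfig(nIndividuals = 6, seed = 3))
#' table(coh$subpop)
#' @export
generateCohort <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  n <- config@nIndividuals
  w <- config@subpopWeights
  data.frame(
    id = sprintf("IND%05d", seq_len(n)),
    subpop = sample(names(w), n, replace = TRUE, prob = w),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

## One synthetic family: consensus residues per column, members sampled
## around it with gaps/insertions, flanks, and the residue->column map.
.sampleRange <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
}

.generateFamily <- function(famIdx, config) {
  L <- .sampleRange(config@modelLength)
  M <- .sampleRange(config@membersPerFamily)
  consRes <- sample(AA_ALPHABET20, L, replace = TRUE)
  planted <- config@plantedPositions
  plantedCols <- planted$column[planted$family == famIdx]
  if (any(plantedCols > L))
    stop("planted position outside model length for family ", famIdx)
  nCons <- min(config@conservedPerFamily, L)
  consCols <- sort(unique(c(plantedCols,
                            sample(setdiff(seq_len(L), plantedCols),
                                   max(0L, nCons - length(plantedCols))))))
  pCons <- ifelse(seq_len(L) %in% consCols, config@consHigh, config@consLow)

  members <- data.frame(protein = sprintf("FAM%02dP%02d", famIdx, seq_len(M)),
                        start = NA_integer_, end = NA_integer_,
                        stringsAsFactors = FALSE)
  columnMaps <- vector("list", M)
  residueMatrix <- matrix(NA_character_, M, L,
                          dimnames = list(members$protein, NULL))
  seqs <- character(M)
  for (m in seq_len(M)) {
    useCons <- stats::runif(L) < pCons
    res <- ifelse(useCons, consRes,
                  vapply(consRes, function(r)
                    sample(setdiff(AA_ALPHABET20, r), 1L), ""))
    gap <- stats::runif(L) < config@gapRate & !(seq_len(L) %in% consCols)
    domRes <- character(0)
    domCol <- integer(0)
    for (j in seq_len(L)) {
      if (!gap[j]) {
        domRes <- c(domRes, res[j]); domCol <- c(domCol, j)
        residueMatrix[m, j] <- res[j]
      }
      if (stats::runif(1) < config@insRate) {
        nIns <- sample(3L, 1L)
        domRes <- c(domRes, sample(AA_ALPHABET20, nIns, replace = TRUE))
        domCol <- c(domCol, rep(NA_integer_, nIns))
      }
    }
    nFlankN <- sample(0:config@flankMax, 1L)
    nFlankC <- sample(0:config@flankMax, 1L)
    seqs[m] <- paste(c(sample(AA_ALPHABET20, nFlankN, TRUE), domRes,
                       sample(AA_ALPHABET20, nFlankC, TRUE)), collapse = "")
    members$start[m] <- nFlankN + 1L
    members$end[m] <- nFlankN + length(domRes)
    columnMaps[[m]] <- domCol
  }
  names(columnMaps) <- members$protein
  fa <- methods::new("FamilyAlignment",
    family = sprintf("FAM%02d", famIdx),
    modelLength = as.integer(L),
    members = members,
    columnMaps = columnMaps,
    residueMatrix = residueMatrix,
    consensus = data.frame())
  fa <- computeConsensus(fa)
  list(alignment = fa, sequences = stats::setNames(seqs, members$protein))
}

## Reverse-translate a protein into a coding sequence, sampling uniformly
## among synonymous codons (no stop codon appended).
.codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

.reverseTranslate <- function(protein, codons) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    opts <- codons[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

#' Generate a synthetic proteome of family alignments
#'
#' Builds the configured number of families. Each member protein carries
#' exactly one domain instance with an explicit residue-to-column map
#' (gaps drop a column, insertions are unmapped residues), random flanks,
#' and a coding sequence whose translation equals the protein. Designated
#' columns (including all planted hotspot columns) are built conserved.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{Proteome}.
#' @examples
#' prot <- generateProteome(syntheticConfig(nFamilies = 2, seed = 2))
#' prot
#' @export
generateProteome <- function(config) {
  methods::validObject(config)
  set.seed(config@seed + 1L)
  fams <- lapply(seq_len(config@nFamilies), .generateFamily, config = config)
  seqs <- unlist(lapply(fams, `[[`, "sequences"))
  codons <- .codonTable()
  cds <- vapply(seqs, .reverseTranslate, "", codons = codons)
  methods::new("Proteome",
    alignments = stats::setNames(lapply(fams, `[[`, "alignment"),
                                 vapply(fams, function(f)
                                   f$alignment@family, "")),
    proteins = Biostrings::AAStringSet(seqs),
    cds = Biostrings::DNAStringSet(cds))
}

## Per-residue missense rate vector for one protein, with planted columns
## multiplied. Returns numeric of protein length.
.residueRates <- function(protein, proteome, config) {
  L <- Biostrings::width(proteome@proteins[protein])
  rates <- rep(config@baseVariantRate, L)
  planted <- config@plantedPositions
  if (!nrow(planted)) return(rates)
  for (fa in proteome@alignments) {
    i <- match(protein, fa@members$protein)
    if (is.na(i)) next
    famIdx <- as.integer(sub("FAM", "", fa@family))
    pp <- planted[planted$family == famIdx, , drop = FALSE]
    if (!nrow(pp)) next
    cm <- fa@columnMaps[[i]]
    for (k in seq_len(nrow(pp))) {
      hit <- which(!is.na(cm) & cm == pp$column[k])
      if (length(hit))
        rates[fa@members$start[i] + hit - 1L] <-
          config@baseVariantRate * pp$multiplier[k]
    }
  }
  rates
}

#' Generate a diploid variant table for a cohort over a proteome
#'
#' Missense variants are drawn independently per haplotype and residue at
#' the base rate (multiplied at planted columns); homozygotes arise by
#' chance when both haplotypes are hit. Stop-gain and frameshift variants
#' are drawn per gene per haplotype at the configured rates and carry a
#' random position with a class marker rather than a residue edit. Every
#' missense ref residue matches the protein sequence.
#'
#' @param proteome a \linkS4class{Proteome} from the same config.
#' @param cohort the data.frame from \code{\link{generateCohort}}.
#' @param config the shared \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{VariantSet}.
#' @examples
#' cfg <- syntheticConfig(nIndividuals = 50, nFamilies = 2, seed = 4)
#' vs <- generateVariants(generateProteome(cfg), generateCohort(cfg), cfg)
#' vs
#' @export
generateVariants <- function(proteome, cohort, config) {
  methods::validObject(config)
  planted <- config@plantedPositions
  if (nrow(planted)) {
    for (k in seq_len(nrow(planted))) {
      fam <- sprintf("FAM%02d", planted$family[k])
      fa <- proteome@alignments[[fam]]
      if (is.null(fa) || planted$column[k] > fa@modelLength)
        stop("planted position outside model length: ", fam,
             " column ", planted$column[k])
    }
  }
  set.seed(config@seed + 2L)
  n <- nrow(cohort)
  nHap <- 2L * n
  proteins <- names(proteome@proteins)
  protSeqs <- as.character(proteome@proteins)

  accProtein <- list(); accPos <- list(); accRef <- list()
  accAlt <- list(); accCons <- list(); genoRows <- list()
  addVariant <- function(protein, pos, ref, alt, cons, hapIdx) {
    ind <- ((hapIdx - 1L) %/% 2L) + 1L
    k <- length(genoRows) + 1L
    accProtein[[k]] <<- protein; accPos[[k]] <<- pos
    accRef[[k]] <<- ref; accAlt[[k]] <<- alt; accCons[[k]] <<- cons
    genoRows[[k]] <<- tabulate(ind, nbins = n)
  }

  for (p in proteins) {
    seqChars <- strsplit(protSeqs[[p]], "")[[1]]
    rates <- .residueRates(p, proteome, config)
    kPerSite <- stats::rbinom(length(rates), nHap, rates)
    for (pos in which(kPerSite > 0L)) {
      hapIdx <- sample.int(nHap, kPerSite[pos])
      ref <- seqChars[pos]
      alt <- sample(setdiff(AA_ALPHABET20, ref), 1L)
      addVariant(p, pos, ref, alt, "missense", hapIdx)
    }
    for (cls in c("stop_gain", "frameshift")) {
      k <- stats::rbinom(1L, nHap, config@lofRates[[cls]])
      if (k > 0L) {
        pos <- sample.int(length(seqChars), 1L)
        addVariant(p, pos, seqChars[pos],
                   if (cls == "stop_gain") "*" else "fs", cls,
                   sample.int(nHap, k))
      }
    }
  }

  if (!length(genoRows)) {
    variants <- data.frame(protein = character(), position = integer(),
                           ref = character(), alt = character(),
                           consequence = character(),
                           stringsAsFactors = FALSE)
    geno <- matrix(integer(0), 0L, n, dimnames = list(NULL, cohort$id))
  } else {
    variants <- data.frame(protein = unlist(accProtein),
                           position = as.integer(unlist(accPos)),
                           ref = unlist(accRef),
                           alt = unlist(accAlt),
                           consequence = unlist(accCons),
                           stringsAsFactors = FALSE)
    geno <- do.call(rbind, genoRows)
    ord <- order(variants$protein, variants$position, variants$alt)
    variants <- variants[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
    rownames(variants) <- NULL
    dimnames(geno) <- list(NULL, cohort$id)
    storage.mode(geno) <- "integer"
  }
  methods::new("VariantSet", variants = variants, geno = geno,
               cohort = cohort)
}

#' Generate a synthetic receptor/odorant screen
#'
#' A fraction of receptors are built non-canonical (a DRY-arginine-lacking
#' class); each receptor x odorant screen is positive with the group's
#' configured rate. Positive screens carry a log10 EC50 uniform in the
#' configured range; negatives carry NA.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param receptors optional receptor identifiers (e.g. proteome member
#'   proteins); defaults to nReceptors synthetic OR names.
#' @return an \linkS4class{OdorScreen} with ground-truth canonical flags.
#' @examples
#' scr <- generateScreen(syntheticConfig(seed = 5))
#' scr
#' @export
generateScreen <- function(config, receptors = NULL) {
  methods::validObject(config)
  set.seed(config@seed + 3L)
  sc <- config@screen
  if (is.null(receptors)) {
    receptors <- sprintf("OR%03d", seq_len(sc$nReceptors))
  } else {
    sc$nReceptors <- length(receptors)
  }
  odorantIds <- sprintf("ODO%03d", seq_len(sc$nOdorants))
  nNC <- round(sc$nonCanonicalFraction * sc$nReceptors)
  canonical <- stats::setNames(rep(TRUE, sc$nReceptors), receptors)
  if (nNC > 0L) canonical[sample(receptors, nNC)] <- FALSE
  tb <- expand.grid(receptor = receptors, odorant = odorantIds,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rate <- ifelse(canonical[tb$receptor], sc$canonicalRate,
                 sc$nonCanonicalRate)
  pos <- stats::runif(nrow(tb)) < rate
  tb$log10Ec50 <- ifelse(pos,
                         stats::runif(nrow(tb), sc$ec50Range[1],
                                      sc$ec50Range[2]),
                         NA_real_)
  methods::new("OdorScreen", table = tb, canonical = canonical)
}
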
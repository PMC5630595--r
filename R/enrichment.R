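#' @include AllClasses.R mapping.R
NULL

#' Expected variant count for a family or a single column
#'
#' The background expectation places alleles uniformly over the proteome:
#' (total alleles / proteome length) x number of domain instances x span,
#' where span is the model length for a whole-family expectation and 1 for
#' a single column.
#'
#' @param totalAlleles pooled alternate-allele count over the proteome.
#' @param proteomeLength total proteome length in residues (> 0).
#' @param nInstances number of domain instances of the family.
#' @param span model length (family) or 1 (column).
#' @return the expected allele count (non-negative real).
#' @examples
#' expectedCount(1000, 10000, 10, 1)   # 1.0
#' expectedCount(1000, 10000, 10, 50)  # 50
#' @export
expectedCount <- function(totalAlleles, proteomeLength, nInstances, span) {
  if (proteomeLength <= 0) stop("proteomeLength must be > 0")
  (totalAlleles / proteomeLength) * nInstances * span
}

#' Base-2 log-odds of observed over expected counts
#'
#' @param observed observed allele count (>= 0).
#' @param expected expected allele count (> 0).
#' @return log2(observed / expected); -Inf when observed is 0.
#' @examples
#' logOdds(8, 8)   # 0
#' logOdds(16, 8)  # 1: the enrichment threshold
#' @export
logOdds <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected must be > 0")
  ifelse(observed == 0, -Inf, log2(observed / expected))
}

## Global column index across families: offsets[family] + column.
.columnIndexing <- function(alignments) {
  lens <- vapply(alignments, function(fa) fa@modelLength, 0L)
  offsets <- c(0L, cumsum(lens))[seq_along(lens)]
  names(offsets) <- names(lens) <- vapply(alignments, function(fa)
    fa@family, "")
  list(offsets = offsets, lengths = lens, total = sum(lens))
}

## Shuffle engine: relocate each protein's pooled missense alleles
## uniformly within that protein, nShuffles times, and count landings on
## every mapped (family, column). Returns a list with the per-trial
## landings matrix (trials x global columns) and per-family totals.
.shuffleLandings <- function(vs, proteome, nShuffles, seed) {
  set.seed(seed)
  alignments <- proteome@alignments
  cidx <- .columnIndexing(alignments)
  idx <- domainIndex(alignments)
  inst <- idx$instances
  mis <- vs@variants$consequence == "missense"
  pooled <- alleleCounts(vs)[mis]
  prot <- vs@variants$protein[mis]
  allelesPerProtein <- tapply(pooled, prot, sum)
  allelesPerProtein <- allelesPerProtein[allelesPerProtein > 0]
  protLen <- stats::setNames(Biostrings::width(proteome@proteins),
                             names(proteome@proteins))
  landings <- matrix(0, nShuffles, cidx$total)
  famLandings <- matrix(0, nShuffles, length(alignments),
                        dimnames = list(NULL, names(cidx$lengths)))
  instByProt <- split(seq_len(nrow(inst)), inst$protein)
  for (p in names(allelesPerProtein)) {
    rows <- instByProt[[p]]
    if (is.null(rows)) next
    A <- allelesPerProtein[[p]]
    L <- protLen[[p]]
    for (s in seq_len(nShuffles)) {
      posTab <- tabulate(sample.int(L, A, replace = TRUE), nbins = L)
      for (i in rows) {
        cm <- idx$maps[[i]]
        ok <- !is.na(cm)
        if (!any(ok)) next
        res <- (inst$start[i]:inst$end[i])[ok]
        gidx <- cidx$offsets[[inst$family[i]]] + cm[ok]
        cnt <- posTab[res]
        landings[s, gidx] <- landings[s, gidx] + cnt
        famLandings[s, inst$family[i]] <-
          famLandings[s, inst$family[i]] + sum(cnt)
      }
    }
  }
  list(columns = landings, families = famLandings, indexing = cidx,
       totalAlleles = sum(pooled))
}

#' Shuffle-prior success probability for the binomial enrichment test
#'
#' Estimates the per-allele probability of landing on a target family or
#' column under the null by relocating every individual's missense alleles
#' uniformly at random within their own protein (collisions allowed) and
#' averaging the fraction of alleles that land on the target.
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param proteome a \linkS4class{Proteome}.
#' @param family target family identifier.
#' @param column target column, or NULL for the whole family.
#' @param nShuffles number of shuffles (>= 1).
#' @param seed RNG seed.
#' @return the mean landing fraction, with the per-trial fractions in
#'   attribute \code{"perTrial"}.
#' @export
shufflePrior <- function(vs, proteome, family, column = NULL,
                         nShuffles = 100L, seed = 1L) {
  stopifnot(nShuffles >= 1L)
  sh <- .shuffleLandings(vs, proteome, nShuffles, seed)
  if (sh$totalAlleles == 0) return(structure(0, perTrial = rep(0, nShuffles)))
  perTrial <- if (is.null(column)) {
    sh$families[, family] / sh$totalAlleles
  } else {
    sh$columns[, sh$indexing$offsets[[family]] + column] / sh$totalAlleles
  }
  structure(mean(perTrial), perTrial = perTrial)
}

#' Upper-tail binomial p-value
#'
#' P(X >= k) for X ~ Binomial(n, prior); enrichment is one-sided upward.
#'
#' @param k observed successes (0 <= k <= n).
#' @param n number of trials.
#' @param prior per-trial success probability.
#' @return the upper-tail probability.
#' @examples
#' binomialPvalue(2, 2, 0.5)  # 0.25
#' @export
binomialPvalue <- function(k, n, prior) {
  stopifnot(all(k >= 0), all(k <= n), all(prior >= 0), all(prior <= 1))
  stats::pbinom(k - 1, n, prior, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up BH with monotone enforcement, order-preserving with
#' respect to the input.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return the q-values, same order as \code{p}.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))
#' @export
bhFdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Per-column variant enrichment over a proteome
#'
#' The central analysis: maps every missense variant onto family alignment
#' columns, counts observed pooled alleles per column, computes the
#' uniform-placement expectation, base-2 log-odds, a shuffle-prior binomial
#' p-value (trials = total pooled missense alleles, success probability =
#' per-column shuffle prior), and BH q-values over the tested set (columns
#' with observed >= minObserved OR expected >= minExpected). Loss-of-
#' function variants are excluded from counting. A per-family table is
#' computed the same way with span = model length.
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param proteome a \linkS4class{Proteome}.
#' @param nShuffles shuffles for the null prior.
#' @param seed RNG seed for the shuffles.
#' @param minObserved,minExpected count floors defining the tested set
#'   (default 50 observed or 5 expected).
#' @param conservationThreshold modal-frequency cutoff for the conserved
#'   flag.
#' @return list with \code{columns} and \code{families} data.frames. The
#'   column table has family, column, observed, expected, logOdds, prior,
#'   pValue, qValue (NA outside the tested set), nGenesWithVariants,
#'   conserved, consensusResidue.
#' @export
positionEnrichment <- function(vs, proteome, nShuffles = 100L, seed = 1L,
                               minObserved = 50, minExpected = 5,
                               conservationThreshold = 0.5) {
  alignments <- lapply(proteome@alignments, computeConsensus,
                       threshold = conservationThreshold)
  cidx <- .columnIndexing(alignments)
  idx <- domainIndex(alignments)
  proteomeLength <- sum(Biostrings::width(proteome@proteins))

  v <- vs@variants
  mis <- which(v$consequence == "missense")
  pooled <- alleleCounts(vs)
  totalAlleles <- sum(pooled[mis])
  hits <- .mapAllVariants(v[mis, , drop = FALSE], idx)
  hits$pooled <- pooled[mis][hits$variantRow]
  hits$protein <- v$protein[mis][hits$variantRow]
  hits$gidx <- cidx$offsets[hits$family] + hits$column

  observed <- numeric(cidx$total)
  if (nrow(hits)) {
    agg <- tapply(hits$pooled, hits$gidx, sum)
    observed[as.integer(names(agg))] <- agg
  }
  nGenes <- integer(cidx$total)
  if (nrow(hits)) {
    carriers <- hits[hits$pooled > 0, , drop = FALSE]
    ng <- tapply(carriers$protein, carriers$gidx,
                 function(x) length(unique(x)))
    nGenes[as.integer(names(ng))] <- ng
  }

  nInstances <- table(idx$instances$family)
  famNames <- names(cidx$lengths)
  colTab <- do.call(rbind, lapply(famNames, function(f) {
    L <- cidx$lengths[[f]]
    cons <- alignments[[f]]@consensus
    data.frame(family = f, column = seq_len(L),
               nInstances = as.integer(nInstances[[f]]),
               conserved = cons$conserved,
               consensusResidue = cons$residue,
               stringsAsFactors = FALSE)
  }))
  colTab$observed <- observed
  colTab$expected <- expectedCount(totalAlleles, proteomeLength,
                                   colTab$nInstances, 1)
  colTab$logOdds <- logOdds(colTab$observed, colTab$expected)
  colTab$nGenesWithVariants <- nGenes

  sh <- .shuffleLandings(vs, proteome, nShuffles, seed)
  colTab$prior <- colMeans(sh$columns) / max(1, totalAlleles)
  colTab$pValue <- binomialPvalue(colTab$observed, totalAlleles,
                                  colTab$prior)
  tested <- colTab$observed >= minObserved | colTab$expected >= minExpected
  colTab$qValue <- NA_real_
  colTab$qValue[tested] <- bhFdr(colTab$pValue[tested])

  famTab <- data.frame(family = famNames,
                       modelLength = as.integer(cidx$lengths),
                       nInstances = as.integer(nInstances[famNames]),
                       stringsAsFactors = FALSE)
  famObs <- vapply(famNames, function(f) {
    rng <- cidx$offsets[[f]] + seq_len(cidx$lengths[[f]])
    sum(observed[rng])
  }, 0)
  famTab$observed <- famObs
  famTab$expected <- expectedCount(totalAlleles, proteomeLength,
                                   famTab$nInstances, famTab$modelLength)
  famTab$logOdds <- logOdds(famTab$observed, famTab$expected)
  famTab$prior <- colMeans(sh$families)[famNames] / max(1, totalAlleles)
  famTab$pValue <- binomialPvalue(famTab$observed, totalAlleles,
                                  famTab$prior)
  famTab$qValue <- bhFdr(famTab$pValue)
  rownames(colTab) <- rownames(famTab) <- NULL
  list(columns = colTab, families = famTab)
}

#' Filter enriched positions
#'
#' Keeps tested columns (observed >= minObserved OR expected >=
#' minExpected) with logOdds >= minLogOdds, qValue <= maxQ, and (when
#' enabled) at least minMembersWithVariants genes carrying variants. All
#' thresholds are inclusive. Rows are ordered by descending log-odds.
#'
#' @param results the \code{columns} table of
#'   \code{\link{positionEnrichment}} (or the full result list).
#' @param minObserved,minExpected count floors (OR-combined).
#' @param minLogOdds log-odds threshold (base 2).
#' @param maxQ q-value ceiling.
#' @param minMembersWithVariants gene floor; set NA to disable.
#' @return the filtered, ranked subset of \code{results}.
#' @export
enrichedPositions <- function(results, minObserved = 50, minExpected = 5,
                              minLogOdds = 1, maxQ = 0.01,
                              minMembersWithVariants = 10) {
  if (is.list(results) && !is.data.frame(results)) results <- results$columns
  keep <- (results$observed >= minObserved |
           results$expected >= minExpected) &
    results$logOdds >= minLogOdds &
    !is.na(results$qValue) & results$qValue <= maxQ
  if (!is.na(minMembersWithVariants))
    keep <- keep & results$nGenesWithVariants >= minMembersWithVariants
  out <- results[keep, , drop = FALSE]
  out[order(-out$logOdds), , drop = FALSE]
}
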
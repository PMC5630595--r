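#' @include AllClasses.R
NULL

#' EC50 potency weight of a positive screen
#'
#' Weight = -log10(EC50) / 9, clamped to [0, 1]; -9 (1 nM, the strongest
#' potency in the pooled screens) maps to 1 and an absent value (negative
#' screen) to 0.
#'
#' @param log10Ec50 numeric vector of log10 molar EC50 values; NA marks a
#'   negative screen.
#' @return weights in [0, 1].
#' @examples
#' ec50Weight(c(-9, -4.5, 0, NA))  # 1, 0.5, 0, 0
#' @export
ec50Weight <- function(log10Ec50) {
  ifelse(is.na(log10Ec50), 0, pmin(1, pmax(0, -log10Ec50 / 9)))
}

#' Canonical vs non-canonical receptor activity statistics at a column
#'
#' Splits the screens by the receptors' residue status at a conserved
#' column and contrasts positive rates: fold enrichment = canonical
#' positive rate / non-canonical positive rate, and the lower-tail
#' hypergeometric probability of seeing this many or fewer positives among
#' the non-canonical screens (population = all screens at the column,
#' successes = all positives, draws = non-canonical screens). Weighted
#' rates replace counts by summed EC50 weights; the hypergeometric uses
#' unweighted counts only.
#'
#' @param screen an \linkS4class{OdorScreen} (or its table).
#' @param status named character (receptor -> "canonical" /
#'   "non_canonical" / "unknown"); unknowns are dropped.
#' @return one-row data.frame: screen and positive counts per group,
#'   weighted positives per group, foldEnrichment (Inf when the
#'   non-canonical rate is 0), hypergeomP.
#' @examples
#' # the published DRY contingency: 102/8815 vs 1/1089
#' scr <- data.frame(
#'   receptor = rep(c("can", "non"), c(8815, 1089)),
#'   odorant = "o",
#'   log10Ec50 = c(rep(-9, 102), rep(NA, 8713), -9, rep(NA, 1088)))
#' st <- c(can = "canonical", non = "non_canonical")
#' positionActivityStats(scr, st)[, c("foldEnrichment", "hypergeomP")]
#' @export
positionActivityStats <- function(screen, status) {
  tb <- if (methods::is(screen, "OdorScreen")) screen@table else screen
  st <- status[tb$receptor]
  keep <- !is.na(st) & st != "unknown"
  tb <- tb[keep, , drop = FALSE]
  st <- st[keep]
  pos <- !is.na(tb$log10Ec50)
  w <- ec50Weight(tb$log10Ec50)
  can <- st == "canonical"
  nCan <- sum(can); nNon <- sum(!can)
  kCan <- sum(pos & can); kNon <- sum(pos & !can)
  rateCan <- if (nCan) kCan / nCan else NA_real_
  rateNon <- if (nNon) kNon / nNon else NA_real_
  fold <- if (is.na(rateNon) || is.na(rateCan)) NA_real_
          else if (rateNon == 0) Inf else rateCan / rateNon
  K <- kCan + kNon
  hp <- stats::phyper(kNon, K, nCan + nNon - K, nNon)
  data.frame(
    nCanonicalScreens = nCan, nCanonicalPositive = kCan,
    nNonCanonicalScreens = nNon, nNonCanonicalPositive = kNon,
    weightedCanonicalPositive = sum(w[can]),
    weightedNonCanonicalPositive = sum(w[!can]),
    canonicalRate = rateCan, nonCanonicalRate = rateNon,
    weightedCanonicalRate = if (nCan) sum(w[can]) / nCan else NA_real_,
    weightedNonCanonicalRate = if (nNon) sum(w[!can]) / nNon else NA_real_,
    foldEnrichment = fold, hypergeomP = hp)
}

#' Loss-of-function allele counts per receptor and individual
#'
#' Sums, per receptor, the alternate-allele counts of its loss-of-function
#' variants (stop-gain, frameshift, and any missense variant listed in
#' \code{dryVariants} -- the conserved-arginine changes), capped at 2
#' alleles per receptor.
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param dryVariants integer vector of variant rows (in
#'   \code{variantInfo(vs)}) whose missense change is loss-of-function.
#' @return integer matrix receptors x individuals with values in 0..2.
#' @export
lofAlleleCounts <- function(vs, dryVariants = integer(0)) {
  v <- vs@variants
  lof <- which(v$consequence %in% c("stop_gain", "frameshift"))
  lof <- sort(unique(c(lof, as.integer(dryVariants))))
  receptors <- unique(v$protein)
  out <- matrix(0L, length(receptors), ncol(vs@geno),
                dimnames = list(receptors, colnames(vs@geno)))
  for (i in lof)
    out[v$protein[i], ] <- out[v$protein[i], ] + vs@geno[i, ]
  out[out > 2L] <- 2L
  out
}

#' Missense variant rows at a conserved arginine-like column
#'
#' Convenience selector for the DRY-style loss-of-function class: the
#' missense variants mapping to a given conserved alignment column.
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param index a \code{\link{domainIndex}} (or alignments/Proteome).
#' @param family,column the conserved position.
#' @return integer vector of rows into \code{variantInfo(vs)}.
#' @export
dryVariantRows <- function(vs, index, family, column) {
  .variantsAtColumn(vs, family, column, index, "missense")
}

#' Predicted per-individual odorant response under loss-of-function
#'
#' For each odorant, each binding receptor contributes its EC50 weight
#' once per functional allele copy (heterozygous loss-of-function halves,
#' homozygous zeroes the receptor's contribution); the response is the
#' mean contribution over all (receptor, allele copy) pairs. Odorants with
#' no binding receptor are NA.
#'
#' @param lofCounts loss-of-function allele-count matrix from
#'   \code{\link{lofAlleleCounts}} (receptors x individuals).
#' @param screen an \linkS4class{OdorScreen}; positive records define
#'   which receptors bind which odorant and with what potency.
#' @return numeric matrix odorants x individuals.
#' @export
individualOdorResponse <- function(lofCounts, screen) {
  tb <- if (methods::is(screen, "OdorScreen")) screen@table else screen
  pos <- tb[!is.na(tb$log10Ec50), , drop = FALSE]
  odorantIds <- unique(tb$odorant)
  out <- matrix(NA_real_, length(odorantIds), ncol(lofCounts),
                dimnames = list(odorantIds, colnames(lofCounts)))
  for (o in odorantIds) {
    hit <- pos[pos$odorant == o, , drop = FALSE]
    if (!nrow(hit)) next
    wts <- ec50Weight(hit$log10Ec50)
    # receptors absent from the LoF table carry no LoF allele
    lof <- matrix(0L, nrow(hit), ncol(lofCounts))
    present <- hit$receptor %in% rownames(lofCounts)
    lof[present, ] <- lofCounts[hit$receptor[present], , drop = FALSE]
    functional <- 2 - lof
    out[o, ] <- as.numeric(wts %*% functional) / (2 * nrow(hit))
  }
  out
}

#' Sub-population odorant response matrix, normalized per odorant
#'
#' Averages individual responses within each population group, then
#' divides each odorant's group means by their maximum (rows with an
#' all-zero response stay 0).
#'
#' @param responses odorants x individuals matrix from
#'   \code{\link{individualOdorResponse}}.
#' @param groups character vector of group labels, one per individual
#'   (column order).
#' @return numeric matrix odorants x groups, each row max-normalized to 1
#'   (or all 0).
#' @export
populationOdorMatrix <- function(responses, groups) {
  stopifnot(length(groups) == ncol(responses))
  gm <- vapply(split(seq_along(groups), groups), function(cols)
    rowMeans(responses[, cols, drop = FALSE]), numeric(nrow(responses)))
  if (is.null(dim(gm)))
    gm <- matrix(gm, nrow = nrow(responses),
                 dimnames = list(rownames(responses),
                                 names(split(seq_along(groups), groups))))
  mx <- apply(gm, 1L, max)
  norm <- gm / ifelse(mx == 0 | is.na(mx), 1, mx)
  rownames(norm) <- rownames(responses)
  norm
}
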
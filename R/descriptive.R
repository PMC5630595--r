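#' @include AllClasses.R mapping.R
NULL

## Rows of the variant table mapping to (family, column), by consequence.
.variantsAtColumn <- function(vs, family, column, index,
                              consequences = "missense") {
  v <- vs@variants
  sel <- which(v$consequence %in% consequences)
  if (!length(sel)) return(integer(0))
  hits <- .mapAllVariants(v[sel, , drop = FALSE], index)
  sel[hits$variantRow[hits$family == family & hits$column == column]]
}

#' Fraction of the cohort carrying a variant at an alignment column
#'
#' The fraction of individuals with at least one alternate allele at any
#' variant mapping to the column (a position like the DRY arginine, where
#' every genome carries one, scores 1).
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param family,column the target alignment position.
#' @param index a \code{\link{domainIndex}} (or alignments/Proteome).
#' @param consequences consequence classes counted (default missense).
#' @return fraction in [0, 1].
#' @export
populationFraction <- function(vs, family, column, index,
                               consequences = "missense") {
  rows <- .variantsAtColumn(vs, family, column, index, consequences)
  if (!length(rows)) return(0)
  carrier <- colSums(vs@geno[rows, , drop = FALSE] > 0L) > 0L
  mean(carrier)
}

#' Pairs of individuals with an identical variant spectrum at a column
#'
#' Counts unordered pairs whose genotype vectors over all variants mapping
#' to the column are identical. A position where no two genomes share a
#' spectrum scores 0; with no variants every pair is identical, giving
#' choose(n, 2).
#'
#' @inheritParams populationFraction
#' @return the number of identical unordered pairs.
#' @export
identicalSpectrumPairs <- function(vs, family, column, index,
                                   consequences = "missense") {
  n <- ncol(vs@geno)
  rows <- .variantsAtColumn(vs, family, column, index, consequences)
  if (!length(rows)) return(choose(n, 2))
  g <- vs@geno[rows, , drop = FALSE]
  key <- apply(g, 2L, paste, collapse = ",")
  sum(choose(table(key), 2))
}

#' Fraction of genes in each subgroup with variants at a column
#'
#' Per gene group (e.g. OR vs non-OR receptors), the fraction of genes
#' carrying at least one variant at the column among genes where the
#' column is mapped. Groups with no genes mapping the column return NA.
#'
#' @inheritParams populationFraction
#' @param groups named character vector: protein -> group label (every
#'   gene in exactly one group).
#' @return named numeric of per-group fractions.
#' @export
geneFractionBySubgroup <- function(vs, family, column, index, groups,
                                   consequences = "missense") {
  if (!is.list(index) || is.null(index$instances)) index <- domainIndex(index)
  inst <- index$instances
  fam <- which(inst$family == family)
  mapped <- unique(vapply(fam, function(i) {
    if (any(!is.na(index$maps[[i]]) & index$maps[[i]] == column))
      inst$protein[i] else NA_character_
  }, ""))
  mapped <- mapped[!is.na(mapped)]
  rows <- .variantsAtColumn(vs, family, column, index, consequences)
  carriers <- rows[rowSums(vs@geno[rows, , drop = FALSE]) > 0]
  hitGenes <- unique(vs@variants$protein[carriers])
  allGroups <- unique(groups)
  vapply(stats::setNames(allGroups, allGroups), function(grp) {
    g <- mapped[groups[mapped] == grp]
    if (!length(g)) NA_real_ else mean(g %in% hitGenes)
  }, 0)
}

#' Per-column z-scores of variant counts
#'
#' Standardizes per-column counts against the mean and population standard
#' deviation over the supplied columns (one family / species set at a
#' time), as used to compare positional variant loads across species.
#'
#' @param counts numeric vector of per-column counts (length >= 2).
#' @return z-scores, same order; all zero when the counts are constant.
#' @examples
#' positionZscores(c(0, 0, 0, 10))  # last = 1.732
#' @export
positionZscores <- function(counts) {
  if (length(counts) < 2L) stop("need counts for at least 2 columns")
  mu <- mean(counts)
  sdPop <- sqrt(mean((counts - mu)^2))
  if (sdPop == 0) return(rep(0, length(counts)))
  (counts - mu) / sdPop
}

#' Percentage of residues whose codon contains a CG dinucleotide
#'
#' Within-codon CG only: arginine codons CGU/CGC/CGA/CGG qualify while
#' AGA/AGG do not, which is what makes the DRY arginine hypermutable.
#'
#' @param residues data.frame with columns protein, position (1-based
#'   residue index).
#' @param cds \link[Biostrings]{DNAStringSet} of coding sequences (no stop
#'   codon), named by protein.
#' @return percentage in [0, 100].
#' @examples
#' cds <- Biostrings::DNAStringSet(c(P1 = "CGAAGG"))
#' codonCgFraction(data.frame(protein = "P1", position = 1:2), cds)  # 50
#' @export
codonCgFraction <- function(residues, cds) {
  stopifnot(all(residues$protein %in% names(cds)))
  codons <- vapply(seq_len(nrow(residues)), function(i) {
    p <- residues$position[i]
    as.character(Biostrings::subseq(cds[[residues$protein[i]]],
                                    3L * p - 2L, 3L * p))
  }, "")
  100 * mean(grepl("CG", codons, fixed = TRUE))
}
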
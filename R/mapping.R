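#' @include AllClasses.R
NULL

#' Compute the per-column consensus of a family alignment
#'
#' For every alignment column the modal residue among members aligned there
#' is taken as the consensus; ties break alphabetically by residue letter.
#' A column is conserved when the modal frequency (over aligned members
#' only) reaches \code{threshold}. Columns with no aligned member get an
#' undefined consensus (NA residue, conserved = NA).
#'
#' @param fa a \linkS4class{FamilyAlignment} with at least one member.
#' @param threshold modal-frequency cutoff for the conserved call.
#' @return \code{fa} with its \code{consensus} slot filled: a data.frame
#'   with columns column, residue, frequency, nAligned, conserved.
#' @examples
#' cfg <- syntheticConfig(nFamilies = 1, seed = 1)
#' fa <- generateProteome(cfg)@alignments[[1]]
#' head(consensus(fa))
#' @export
computeConsensus <- function(fa, threshold = 0.5) {
  stopifnot(nrow(fa@members) >= 1L)
  L <- fa@modelLength
  res <- character(L); freq <- numeric(L); nAl <- integer(L)
  for (j in seq_len(L)) {
    col <- fa@residueMatrix[, j]
    col <- col[!is.na(col)]
    nAl[j] <- length(col)
    if (!length(col)) {
      res[j] <- NA_character_; freq[j] <- NA_real_
      next
    }
    tab <- table(col)
    top <- max(tab)
    # alphabetical tie-break: table() names are already sorted
    res[j] <- names(tab)[which(tab == top)[1L]]
    freq[j] <- top / length(col)
  }
  fa@consensus <- data.frame(
    column = seq_len(L), residue = res, frequency = freq,
    nAligned = nAl, conserved = ifelse(nAl == 0L, NA, freq >= threshold),
    stringsAsFactors = FALSE)
  fa
}

#' Index domain instances by protein
#'
#' Flattens a list of \linkS4class{FamilyAlignment} into one table of
#' domain instances for fast lookup, keeping the residue-to-column maps.
#'
#' @param alignments list of \linkS4class{FamilyAlignment} (or a
#'   \linkS4class{Proteome}).
#' @return list with \code{instances} (data.frame: family, protein, start,
#'   end, idx) and \code{maps} (list of integer vectors parallel to rows).
#' @export
domainIndex <- function(alignments) {
  if (methods::is(alignments, "Proteome")) alignments <- alignments@alignments
  inst <- list(); maps <- list()
  for (fa in alignments) {
    m <- fa@members
    for (i in seq_len(nrow(m))) {
      k <- length(maps) + 1L
      inst[[k]] <- data.frame(family = fa@family, protein = m$protein[i],
                              start = m$start[i], end = m$end[i],
                              stringsAsFactors = FALSE)
      maps[[k]] <- fa@columnMaps[[i]]
    }
  }
  instances <- if (length(inst)) do.call(rbind, inst) else
    data.frame(family = character(), protein = character(),
               start = integer(), end = integer())
  instances$idx <- seq_len(nrow(instances))
  list(instances = instances, maps = maps)
}

#' Map a protein change onto family alignment columns
#'
#' Returns every (family, column) pair whose domain instance covers the
#' residue position with a mapped (non-insertion) column. A protein with
#' two instances of one family yields two hits. Positions outside all
#' instances, or at insertion residues, return an empty result; this is
#' not an error. Stop-gain/frameshift variants map identically and are
#' distinguished only by their consequence class.
#'
#' @param protein protein identifier.
#' @param position 1-based residue position.
#' @param index a \code{\link{domainIndex}} (or the alignments/Proteome to
#'   build one from).
#' @return data.frame with columns family, column (0 rows for no hit).
#' @examples
#' cfg <- syntheticConfig(nFamilies = 1, seed = 1)
#' prot <- generateProteome(cfg)
#' idx <- domainIndex(prot)
#' mapVariantToColumn(idx$instances$protein[1], idx$instances$start[1], idx)
#' @export
mapVariantToColumn <- function(protein, position, index) {
  if (!is.list(index) || is.null(index$instances)) index <- domainIndex(index)
  inst <- index$instances
  hit <- which(inst$protein == protein & inst$start <= position &
               inst$end >= position)
  out <- data.frame(family = character(), column = integer(),
                    stringsAsFactors = FALSE)
  for (i in hit) {
    col <- index$maps[[i]][position - inst$start[i] + 1L]
    if (!is.na(col))
      out <- rbind(out, data.frame(family = inst$family[i],
                                   column = as.integer(col),
                                   stringsAsFactors = FALSE))
  }
  out
}

## Vectorized mapping of a whole variant table: returns one row per
## (variant, instance) hit with the variant's row index attached.
.mapAllVariants <- function(variants, index) {
  if (!is.list(index) || is.null(index$instances)) index <- domainIndex(index)
  inst <- index$instances
  out <- list()
  byProt <- split(seq_len(nrow(inst)), inst$protein)
  for (v in seq_len(nrow(variants))) {
    rows <- byProt[[variants$protein[v]]]
    if (is.null(rows)) next
    pos <- variants$position[v]
    for (i in rows) {
      if (inst$start[i] <= pos && inst$end[i] >= pos) {
        col <- index$maps[[i]][pos - inst$start[i] + 1L]
        if (!is.na(col))
          out[[length(out) + 1L]] <- c(v, i, col)
      }
    }
  }
  if (!length(out))
    return(data.frame(variantRow = integer(), family = character(),
                      column = integer(), stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  data.frame(variantRow = m[, 1], family = inst$family[m[, 2]],
             column = as.integer(m[, 3]), stringsAsFactors = FALSE)
}

#' Canonical/non-canonical residue status of a receptor at columns
#'
#' A receptor is canonical at a column when its residue there equals the
#' family consensus residue (the DRY-arginine check generalised to any
#' conserved column). Columns unmapped in the receptor (gap or insertion)
#' return "unknown".
#'
#' @param receptorSequence the receptor's full protein sequence (character
#'   or AAString).
#' @param fa a \linkS4class{FamilyAlignment} whose consensus is computed
#'   and which contains the receptor as a member.
#' @param columns integer vector of alignment columns to check.
#' @param receptor receptor (protein) identifier naming the member.
#' @return data.frame: column, residue, consensusResidue, status in
#'   {canonical, non_canonical, unknown}.
#' @export
canonicalCheck <- function(receptorSequence, fa, columns,
                           receptor = names(receptorSequence)[1]) {
  if (!nrow(fa@consensus)) fa <- computeConsensus(fa)
  i <- match(receptor, fa@members$protein)
  if (is.na(i)) stop("receptor ", receptor, " is not a member of ",
                     fa@family)
  seqChars <- strsplit(as.character(receptorSequence)[1], "")[[1]]
  cm <- fa@columnMaps[[i]]
  start <- fa@members$start[i]
  out <- data.frame(column = as.integer(columns),
                    residue = NA_character_,
                    consensusResidue =
                      fa@consensus$residue[match(columns,
                                                 fa@consensus$column)],
                    status = "unknown", stringsAsFactors = FALSE)
  for (k in seq_along(columns)) {
    off <- which(!is.na(cm) & cm == columns[k])
    if (length(off) == 1L) {
      r <- seqChars[start + off - 1L]
      out$residue[k] <- r
      out$status[k] <- if (identical(r, out$consensusResidue[k]))
        "canonical" else "non_canonical"
    }
  }
  out
}
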
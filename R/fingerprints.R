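#' @include AllClasses.R
NULL

#' Build per-individual allelic fingerprints
#'
#' Fixed-order vectors over the selected variants, one per individual:
#' binary mode (default) records carrier status (>= 1 alternate allele),
#' diploid mode the allele count in {0, 1, 2}. Variant order is
#' deterministic: by protein, position, then alt.
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param selection integer vector of variant rows, or one of "lof" (stop,
#'   frameshift), "all"; defaults to "all".
#' @param mode "binary" or "diploid".
#' @return integer matrix individuals x variants; column names encode
#'   protein:position:alt.
#' @export
buildFingerprints <- function(vs, selection = "all",
                              mode = c("binary", "diploid")) {
  mode <- match.arg(mode)
  v <- vs@variants
  if (is.character(selection) && length(selection) == 1L) {
    selection <- switch(selection,
      all = seq_len(nrow(v)),
      lof = which(v$consequence %in% c("stop_gain", "frameshift")),
      stop("unknown selection keyword"))
  }
  stopifnot(length(selection) >= 1L)
  ord <- selection[order(v$protein[selection], v$position[selection],
                         v$alt[selection])]
  fp <- t(vs@geno[ord, , drop = FALSE])
  if (mode == "binary") fp <- (fp > 0L) * 1L
  colnames(fp) <- paste(v$protein[ord], v$position[ord], v$alt[ord],
                        sep = ":")
  storage.mode(fp) <- "integer"
  fp
}

#' Sum-of-absolute-differences distance between two fingerprints
#'
#' The Manhattan distance; in binary mode this is the Hamming distance.
#'
#' @param a,b equal-length numeric vectors.
#' @return non-negative distance.
#' @examples
#' fingerprintDistance(c(1, 0, 1), c(0, 0, 1))  # 1
#' @export
fingerprintDistance <- function(a, b) {
  stopifnot(length(a) == length(b))
  sum(abs(a - b))
}

#' Complete-linkage hierarchical clustering of fingerprints
#'
#' Manhattan (sum of absolute differences) distances, complete linkage.
#'
#' @param fp individuals x variants fingerprint matrix (>= 2 rows).
#' @return an \code{\link[stats]{hclust}} tree.
#' @export
clusterIndividuals <- function(fp) {
  stopifnot(nrow(fp) >= 2L)
  stats::hclust(stats::dist(fp, method = "manhattan"),
                method = "complete")
}

#' Cut a dendrogram at a depth
#'
#' Clusters are the connected components after removing merges above the
#' depth (in fingerprint bits), e.g. the published 35-bit cut for the
#' DRY-variant fingerprints and 100 for all OR variants.
#'
#' @param hc an \code{\link[stats]{hclust}} tree.
#' @param depth height cutoff (>= 0).
#' @return integer cluster assignment named by individual.
#' @export
cutClusters <- function(hc, depth) {
  stopifnot(depth >= 0)
  stats::cutree(hc, h = depth)
}

#' Export a dendrogram as Newick
#'
#' @param hc an \code{\link[stats]{hclust}} tree.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Per-cluster variant enrichment and depletion
#'
#' For every variant and cluster (or super-population label), the base-2
#' log-odds of the carrier frequency inside the cluster versus the rest of
#' the population. Variants at or beyond +/- threshold are flagged
#' enriched / depleted. A zero outside frequency with carriers inside
#' gives +Inf (reported, not dropped); zero/zero gives NA.
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param clusters integer or character assignment, one per individual in
#'   cohort order (dendrogram cut or super-population labels).
#' @param selection variant rows as in \code{\link{buildFingerprints}}.
#' @param threshold log-odds magnitude for the enriched/depleted call.
#' @return data.frame: cluster, variant, freqIn, freqOut, logOdds, status.
#' @export
clusterVariantEnrichment <- function(vs, clusters, selection = "all",
                                     threshold = 0.6) {
  stopifnot(length(clusters) == ncol(vs@geno))
  if (length(unique(clusters)) < 2L)
    stop("need at least 2 clusters")
  fp <- buildFingerprints(vs, selection, mode = "binary")
  out <- list()
  for (cl in sort(unique(clusters))) {
    inside <- clusters == cl
    fIn <- colMeans(fp[inside, , drop = FALSE])
    fOut <- colMeans(fp[!inside, , drop = FALSE])
    lo <- ifelse(fIn == 0 & fOut == 0, NA_real_,
          ifelse(fOut == 0, Inf,
          ifelse(fIn == 0, -Inf, log2(fIn / fOut))))
    status <- ifelse(is.na(lo), "none",
              ifelse(lo >= threshold, "enriched",
              ifelse(lo <= -threshold, "depleted", "none")))
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, variant = colnames(fp), freqIn = fIn,
      freqOut = fOut, logOdds = lo, status = status,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
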
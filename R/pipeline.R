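#' @include AllClasses.R
NULL

#' Run the full synthetic-study pipeline
#'
#' Orchestrates the stages synth (generate and write the synthetic study),
#' map/enrich (position enrichment tables), pharm (activity statistics and
#' anosmia responses), cluster (fingerprint dendrogram, cuts, per-cluster
#' enrichment) and abm (odorant-driven simulation metrics). Stages
#' communicate via files under \code{outDir}; a JSON manifest with MD5
#' checksums of every artifact is written last, so re-runs with the same
#' seed and config are checksum-identical.
#'
#' @param outDir output directory.
#' @param config a \linkS4class{SyntheticConfig} (its seed is combined
#'   with \code{seed}).
#' @param stages subset of c("synth", "enrich", "pharm", "cluster",
#'   "abm").
#' @param seed global seed folded into every stage.
#' @param nShuffles shuffles for the enrichment prior.
#' @param clusterDepth dendrogram depth cut (bits).
#' @param abmSteps simulation steps.
#' @return the manifest, invisibly: a list with \code{files} (named MD5
#'   checksums) and \code{parameters}.
#' @export
runPipeline <- function(outDir,
                        config = syntheticConfig(nIndividuals = 200L,
                                                 nFamilies = 5L),
                        stages = c("synth", "enrich", "pharm", "cluster",
                                   "abm"),
                        seed = 1L, nShuffles = 50L, clusterDepth = 35,
                        abmSteps = 50L) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  config@seed <- as.integer(config@seed + seed)
  files <- character(0)
  addCsv <- function(x, name) {
    p <- file.path(outDir, name)
    utils::write.csv(x, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }

  cohortDf <- generateCohort(config)
  proteome <- generateProteome(config)
  vs <- generateVariants(proteome, cohortDf, config)
  # screen the members of the planted (OR-like) family as receptors
  orFamily <- sprintf("FAM%02d",
                      if (nrow(config@plantedPositions))
                        config@plantedPositions$family[1] else 1L)
  receptors <- proteome@alignments[[orFamily]]@members$protein
  screen <- generateScreen(config, receptors = receptors)

  if ("synth" %in% stages)
    files <- c(files, writeStudy(proteome, vs, screen, outDir))

  if ("enrich" %in% stages) {
    enr <- positionEnrichment(vs, proteome, nShuffles = nShuffles,
                              seed = seed)
    addCsv(enr$columns, "enrichment_columns.csv")
    addCsv(enr$families, "enrichment_families.csv")
    addCsv(enrichedPositions(enr, minMembersWithVariants = NA),
           "enriched_positions.csv")
  }

  if ("pharm" %in% stages) {
    status <- ifelse(screen@canonical, "canonical", "non_canonical")
    addCsv(positionActivityStats(screen, status), "activity_stats.csv")
    idx <- domainIndex(proteome)
    dryCol <- if (nrow(config@plantedPositions))
      config@plantedPositions$column[1] else 1L
    dry <- dryVariantRows(vs, idx, orFamily, dryCol)
    lof <- lofAlleleCounts(vs, dryVariants = dry)
    resp <- individualOdorResponse(lof, screen)
    addCsv(as.data.frame(resp), "odor_responses.csv")
    addCsv(as.data.frame(populationOdorMatrix(resp, cohortDf$subpop)),
           "population_odor_matrix.csv")
  }

  if ("cluster" %in% stages && nrow(vs@variants) >= 1L) {
    fp <- buildFingerprints(vs, "all")
    hc <- clusterIndividuals(fp)
    nwk <- file.path(outDir, "dendrogram.nwk")
    writeNewick(hc, nwk)
    files <- c(files, nwk)
    cl <- cutClusters(hc, clusterDepth)
    addCsv(data.frame(id = names(cl), cluster = as.integer(cl)),
           "clusters.csv")
    if (length(unique(vs@cohort$subpop)) >= 2L)
      addCsv(clusterVariantEnrichment(vs, vs@cohort$subpop),
             "subpop_variant_enrichment.csv")
  }

  if ("abm" %in% stages) {
    w <- initWorld(seed = seed)
    run <- runWorld(w, abmSteps)
    addCsv(run$metrics, "abm_metrics.csv")
  }

  manifest <- list(
    parameters = list(seed = seed, nShuffles = nShuffles,
                      clusterDepth = clusterDepth, abmSteps = abmSteps,
                      nIndividuals = config@nIndividuals,
                      nFamilies = config@nFamilies,
                      configSeed = config@seed),
    files = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
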
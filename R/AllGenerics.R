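#' @include AllClasses.R
NULL

#' Accessors for famvar classes
#'
#' Small accessor family: \code{variantInfo} returns the variant table,
#' \code{genotypes} the allele-count matrix, \code{cohort} the individual
#' table, \code{alleleCounts} the pooled alternate-allele count per variant,
#' \code{consensus} the per-column consensus table, \code{familyMembers} the
#' member/domain-instance table, \code{modelLength} the number of alignment
#' columns, \code{screenTable} the receptor/odorant table, \code{animals}
#' and \code{odorants} the agent and source tables of a simulation world.
#'
#' @param x a famvar object.
#' @return the slot contents described above.
#' @name accessors
#' @rdname accessors
#' @examples
#' cfg <- syntheticConfig(nIndividuals = 10, nFamilies = 1, seed = 1)
#' coh <- generateCohort(cfg)
#' head(coh)
NULL

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("cohort", function(x) standardGeneric("cohort"))
#' @rdname accessors
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))
#' @rdname accessors
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))
#' @rdname accessors
#' @export
setGeneric("familyMembers", function(x) standardGeneric("familyMembers"))
#' @rdname accessors
#' @export
setGeneric("modelLength", function(x) standardGeneric("modelLength"))
#' @rdname accessors
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))
#' @rdname accessors
#' @export
setGeneric("animals", function(x) standardGeneric("animals"))
#' @rdname accessors
#' @export
setGeneric("odorants", function(x) standardGeneric("odorants"))

#' @rdname accessors
#' @export
setMethod("variantInfo", "VariantSet", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("genotypes", "VariantSet", function(x) x@geno)
#' @rdname accessors
#' @export
setMethod("cohort", "VariantSet", function(x) x@cohort)
#' @rdname accessors
#' @export
setMethod("alleleCounts", "VariantSet", function(x) {
  if (nrow(x@geno) == 0L) return(integer(0))
  as.integer(rowSums(x@geno))
})
#' @rdname accessors
#' @export
setMethod("consensus", "FamilyAlignment", function(x) x@consensus)
#' @rdname accessors
#' @export
setMethod("familyMembers", "FamilyAlignment", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("modelLength", "FamilyAlignment", function(x) x@modelLength)
#' @rdname accessors
#' @export
setMethod("screenTable", "OdorScreen", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("animals", "OdorWorld", function(x) worldAnimals(x))
#' @rdname accessors
#' @export
setMethod("odorants", "OdorWorld", function(x) x@odorants)

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nIndividuals, "individuals,",
      object@nFamilies, "families\n")
  cat("  subpops:", paste(sprintf("%s=%.2f", names(object@subpopWeights),
                                  object@subpopWeights), collapse = " "), "\n")
  cat("  base missense rate:", object@baseVariantRate,
      "| planted positions:", nrow(object@plantedPositions), "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "FamilyAlignment", function(object) {
  cat("FamilyAlignment", object@family, "with", nrow(object@members),
      "members over", object@modelLength, "columns\n")
  if (nrow(object@consensus))
    cat("  conserved columns:", sum(object@consensus$conserved), "\n")
})

setMethod("show", "Proteome", function(object) {
  cat("Proteome:", length(object@alignments), "families,",
      length(object@proteins), "proteins\n")
})

setMethod("show", "VariantSet", function(object) {
  tab <- table(factor(object@variants$consequence,
                      c("missense", "stop_gain", "frameshift")))
  cat("VariantSet:", nrow(object@variants), "variants x",
      ncol(object@geno), "individuals\n")
  cat("  missense:", tab[["missense"]], " stop_gain:", tab[["stop_gain"]],
      " frameshift:", tab[["frameshift"]], "\n")
})

setMethod("show", "OdorScreen", function(object) {
  tb <- object@table
  cat("OdorScreen:", nrow(tb), "screens,",
      length(unique(tb$receptor)), "receptors,",
      length(unique(tb$odorant)), "odorants;",
      sum(!is.na(tb$log10Ec50)), "positive\n")
})

setMethod("show", "OdorWorld", function(object) {
  e <- object@params$env
  cat("OdorWorld", paste(object@gridDim, collapse = "x"), "grid |",
      e$n, "animals,", nrow(object@odorants),
      "odorant sources | step", e$step, "\n")
})
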
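#' Accessors for DimorphScreen classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a DimorphScreen S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nuclearChannel", function(object) standardGeneric("nuclearChannel"))
#' @rdname accessors
#' @export
setMethod("nuclearChannel", "GutImage", function(object) object@nuclear)

#' @rdname accessors
#' @export
setGeneric("gfpChannel", function(object) standardGeneric("gfpChannel"))
#' @rdname accessors
#' @export
setMethod("gfpChannel", "GutImage", function(object) object@gfp)

#' @rdname accessors
#' @export
setGeneric("imageEndpoints", function(object) standardGeneric("imageEndpoints"))
#' @rdname accessors
#' @export
setMethod("imageEndpoints", "GutImage", function(object) object@endpoints)

#' @rdname accessors
#' @export
setGeneric("gutSex", function(object) standardGeneric("gutSex"))
#' @rdname accessors
#' @export
setMethod("gutSex", "GutImage", function(object) object@sex)
#' @rdname accessors
#' @export
setMethod("gutSex", "GutQuantification", function(object) object@sex)

#' @rdname accessors
#' @export
setGeneric("gutLength", function(object) standardGeneric("gutLength"))
#' @rdname accessors
#' @export
setMethod("gutLength", "GutQuantification", function(object) object@lengthPx)

#' @rdname accessors
#' @export
setGeneric("cellTable", function(object) standardGeneric("cellTable"))
#' @rdname accessors
#' @export
setMethod("cellTable", "GutQuantification", function(object) object@cells)

#' @rdname accessors
#' @param which `"total"` (all nuclei) or `"gfp"` (GFP+ EECs).
#' @export
setGeneric("decileCounts", function(object, which = "gfp")
  standardGeneric("decileCounts"))
#' @rdname accessors
#' @export
setMethod("decileCounts", "GutQuantification", function(object, which = "gfp") {
  which <- match.arg(which, c("gfp", "total"))
  if (which == "gfp") object@decileCountsGFP else object@decileCountsTotal
})

#' @rdname accessors
#' @export
setGeneric("enrichmentRatios", function(object)
  standardGeneric("enrichmentRatios"))
#' @rdname accessors
#' @export
setMethod("enrichmentRatios", "EnrichmentResult", function(object) object@ratio)

#' @rdname accessors
#' @export
setGeneric("lengthRatio", function(object) standardGeneric("lengthRatio"))
#' @rdname accessors
#' @export
setMethod("lengthRatio", "EnrichmentResult", function(object) object@lengthRatio)

#' @rdname accessors
#' @export
setGeneric("adjustedPValues", function(object)
  standardGeneric("adjustedPValues"))
#' @rdname accessors
#' @export
setMethod("adjustedPValues", "EnrichmentResult",
          function(object) object@pAdjusted)

#' @rdname accessors
#' @export
setGeneric("hitCalls", function(object) standardGeneric("hitCalls"))
#' @rdname accessors
#' @export
setMethod("hitCalls", "HitTable", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("hitCutoff", function(object) standardGeneric("hitCutoff"))
#' @rdname accessors
#' @export
setMethod("hitCutoff", "HitTable", function(object) object@cutoff)

#' @rdname accessors
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setMethod("profileValues", "ProfileMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("profileRowInfo", function(object) standardGeneric("profileRowInfo"))
#' @rdname accessors
#' @export
setMethod("profileRowInfo", "ProfileMatrix", function(object) object@rowInfo)
#' @rdname accessors
#' @export
setMethod("profileRowInfo", "PhenoEmbedding", function(object) object@rowInfo)

#' @rdname accessors
#' @export
setGeneric("pcaScores", function(object) standardGeneric("pcaScores"))
#' @rdname accessors
#' @export
setMethod("pcaScores", "PhenoEmbedding", function(object) object@scores)

#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))
#' @rdname accessors
#' @export
setMethod("pcaLoadings", "PhenoEmbedding", function(object) object@loadings)

#' @rdname accessors
#' @export
setGeneric("varExplained", function(object) standardGeneric("varExplained"))
#' @rdname accessors
#' @export
setMethod("varExplained", "PhenoEmbedding",
          function(object) object@varExplained)

setMethod("show", "GutImage", function(object) {
  d <- dim(object@nuclear)
  cat(sprintf("GutImage: %d x %d px, %s (%s), driver %s\n",
              d[1], d[2], object@sex, object@mating, object@driver))
})

setMethod("show", "GutQuantification", function(object) {
  cat(sprintf(
    "GutQuantification: %s gut, length %.1f px, %d nuclei (%d GFP+)\n",
    object@sex, object@lengthPx, nrow(object@cells), sum(object@cells$gfp)))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult: %d female vs %d male guts, length ratio %.3f\n",
    object@nFemale, object@nMale, object@lengthRatio))
  cat("observed/expected by decile:\n")
  print(round(setNames(object@ratio, paste0("d", 1:10)), 3))
})

setMethod("show", "HitTable", function(object) {
  tab <- object@table
  cat(sprintf("HitTable: %d gene x sex x trait records, cutoff |z| > %g\n",
              nrow(tab), object@cutoff))
  cat(sprintf("hits: %d (%.1f%%)\n", sum(tab$hit),
              100 * mean(tab$hit)))
})

setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix (%s): %d profiles x %d traits\n",
              object@mode, nrow(object@values), ncol(object@values)))
})

setMethod("show", "PhenoEmbedding", function(object) {
  cat(sprintf("PhenoEmbedding: %d rows, %d components\n",
              nrow(object@scores), ncol(object@scores)))
  cat("explained variance: ",
      paste(sprintf("%.1f%%", 100 * head(object@varExplained, 4)),
            collapse = ", "), "\n")
})

setMethod("show", "GutSimParams", function(object) {
  cat(sprintf(
    "GutSimParams: male length %g px, ratio %g, %g nuclei/px, seed %d\n",
    object@lengthMalePx, object@lengthRatio, object@nucleiPerPx, object@seed))
  if (length(object@enrichmentDeciles))
    cat(sprintf("  %gx GFP enrichment in deciles {%s} (%s)\n",
                object@enrichmentFold,
                paste(object@enrichmentDeciles, collapse = ","),
                object@enrichmentSex))
})
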
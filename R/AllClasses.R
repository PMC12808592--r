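#' @import methods
#' @importFrom stats aov approx coef cor cor.test dchisq integrate lm mad
#'   median oneway.test p.adjust pnorm predict pt qnorm quantile rbinom rexp
#'   rnorm rpois runif sd setNames spline splinefun t.test TukeyHSD var
#'   cophenetic as.dist hclust rle na.omit
#' @importFrom utils head read.csv read.delim tail write.csv packageVersion
#' @importFrom tools md5sum
#' @useDynLib DimorphScreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parameters for the synthetic gut-image generator
#'
#' Describes the simulated midgut: a curved tube of sex-dependent arc length
#' (female length = `lengthRatio` times the male length, ~1.4 in flies),
#' populated by nuclei at a fixed linear density, a per-decile probability
#' profile that a nucleus belongs to the GFP-labelled EEC subset, and an
#' optional multiplicative enrichment of that probability in selected
#' deciles of one sex (emulating the female mid-gut excess of AstC cells).
#'
#' @slot lengthMalePx male gut arc length in pixels.
#' @slot lengthRatio female:male length ratio.
#' @slot tubeWidthPx tube diameter in pixels.
#' @slot nucleiPerPx linear nucleus density along the axis (nuclei/px).
#' @slot eecFractionProfile length-10 vector of per-decile GFP+ probabilities.
#' @slot enrichmentDeciles 0-based decile indices receiving the enrichment.
#' @slot enrichmentFold multiplicative enrichment factor.
#' @slot enrichmentSex sex to which the enrichment applies.
#' @slot curvature relative amplitude of centerline bending (0 = straight).
#' @slot noiseSd additive Gaussian pixel noise sd (intensity units, [0,1]).
#' @slot blobSigma Gaussian sd of a rendered nucleus, px.
#' @slot minSpacing hard-core minimum distance between nuclei, px.
#' @slot pixelSize physical pixel size, micrometres.
#' @slot seed integer RNG seed.
#' @exportClass GutSimParams
setClass("GutSimParams", representation(
  lengthMalePx = "numeric", lengthRatio = "numeric", tubeWidthPx = "numeric",
  nucleiPerPx = "numeric", eecFractionProfile = "numeric",
  enrichmentDeciles = "integer", enrichmentFold = "numeric",
  enrichmentSex = "character", curvature = "numeric", noiseSd = "numeric",
  blobSigma = "numeric", minSpacing = "numeric", pixelSize = "numeric",
  seed = "integer"))

setValidity("GutSimParams", function(object) {
  p <- object@eecFractionProfile
  if (length(p) != 10L) return("eecFractionProfile must have length 10")
  if (any(p < 0 | p > 1)) return("eecFractionProfile entries must lie in [0, 1]")
  if (object@lengthMalePx <= 0 || object@lengthRatio <= 0 ||
      object@tubeWidthPx <= 0 || object@nucleiPerPx <= 0)
    return("length, ratio, width and density must be positive")
  if (object@enrichmentFold <= 0) return("enrichmentFold must be positive")
  if (object@curvature < 0 || object@noiseSd < 0)
    return("curvature and noiseSd must be nonnegative")
  d <- object@enrichmentDeciles
  if (length(d) && (any(d < 0L) || any(d > 9L)))
    return("enrichmentDeciles must be 0-based indices in 0..9")
  bad <- d[p[d + 1L] * object@enrichmentFold > 1]
  if (length(bad))
    return(sprintf(
      "enrichment fold pushes GFP probability above 1 in decile %s",
      paste(bad, collapse = ", ")))
  if (!object@enrichmentSex %in% c("male", "female"))
    return("enrichmentSex must be 'male' or 'female'")
  TRUE
})

#' Two-channel maximum-projection gut image
#'
#' Holds the nuclear-stain and GFP channels of a projected midgut image,
#' the manually marked anterior/posterior endpoints (cardia and hindgut
#' junction), the pixel size, and grouping labels.
#'
#' @slot nuclear,gfp numeric matrices in [0, 1], indexed `[x, y]`.
#' @slot pixelSize micrometres per pixel.
#' @slot endpoints 2 x 2 matrix; rows = anterior, posterior; columns = x, y.
#' @slot sex `"male"` or `"female"`.
#' @slot mating `"virgin"` or `"mated"`.
#' @slot driver driver/genotype identifier.
#' @exportClass GutImage
setClass("GutImage", representation(
  nuclear = "matrix", gfp = "matrix", pixelSize = "numeric",
  endpoints = "matrix", sex = "character", mating = "character",
  driver = "character"))

setValidity("GutImage", function(object) {
  if (!identical(dim(object@nuclear), dim(object@gfp)))
    return("nuclear and gfp channels must share dimensions")
  ep <- object@endpoints
  if (!identical(dim(ep), c(2L, 2L))) return("endpoints must be a 2 x 2 matrix")
  d <- dim(object@nuclear)
  if (any(ep[, 1] < 1 | ep[, 1] > d[1] | ep[, 2] < 1 | ep[, 2] > d[2]))
    return("endpoints must lie inside the raster")
  if (!object@sex %in% c("male", "female"))
    return("sex must be 'male' or 'female'")
  TRUE
})

#' Quantification of a single gut image
#'
#' @slot lengthPx gut axis arc length, px.
#' @slot cells data.frame with one row per segmented nucleus: `x`, `y`,
#'   `t` (arc-length fraction in [0,1]), `decile` (0-based), `gfp` (logical).
#' @slot decileCountsTotal,decileCountsGFP length-10 integer count vectors.
#' @slot sex,genotype,mating grouping labels.
#' @exportClass GutQuantification
setClass("GutQuantification", representation(
  lengthPx = "numeric", cells = "data.frame",
  decileCountsTotal = "integer", decileCountsGFP = "integer",
  sex = "character", genotype = "character", mating = "character"))

setValidity("GutQuantification", function(object) {
  if (length(object@decileCountsTotal) != 10L ||
      length(object@decileCountsGFP) != 10L)
    return("decile count vectors must have length 10")
  if (sum(object@decileCountsTotal) != nrow(object@cells))
    return("total decile counts must sum to the number of cells")
  if (sum(object@decileCountsGFP) != sum(object@cells$gfp))
    return("GFP decile counts must sum to the number of GFP+ cells")
  if (any(object@cells$t < 0 | object@cells$t > 1))
    return("arc-length fractions must lie in [0, 1]")
  TRUE
})

#' Length-scaled regional enrichment result
#'
#' Per-decile comparison of observed female cell counts against the counts
#' expected if female guts were simply length-scaled male guts: the expected
#' count is the male decile mean times the female:male length ratio, and the
#' observed/expected ratio exceeds 1 where females carry more cells than
#' length alone predicts.
#'
#' @slot lengthRatio mean female length / mean male length.
#' @slot expected expected female counts per decile (length 10).
#' @slot observed observed mean female counts per decile.
#' @slot ratio observed / expected per decile.
#' @slot ciLow,ciHigh percentile bootstrap 95% CI of the ratio.
#' @slot pValues,pAdjusted per-decile Welch t-test p, raw and Holm-Sidak.
#' @slot nFemale,nMale numbers of guts.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult", representation(
  lengthRatio = "numeric", expected = "numeric", observed = "numeric",
  ratio = "numeric", ciLow = "numeric", ciHigh = "numeric",
  pValues = "numeric", pAdjusted = "numeric",
  nFemale = "integer", nMale = "integer"))

#' Screen-wide hit table
#'
#' Per gene x sex x trait z-scores against the sex-matched control, where
#' the scale is the standard deviation across all knockdown means, and hits
#' are calls with |z| strictly greater than the cutoff (1.5 by convention).
#'
#' @slot table data.frame with columns `gene`, `sex`, `trait`, `mean`,
#'   `controlMean`, `z`, `hit`, `sign`.
#' @slot cutoff z-score cutoff (positive).
#' @slot traitSD data.frame of the across-knockdown SD per sex x trait.
#' @exportClass HitTable
setClass("HitTable", representation(
  table = "data.frame", cutoff = "numeric", traitSD = "data.frame"))

#' Phenotype profile matrix for clustering / PCA
#'
#' Rows are gene-by-sex profiles, columns are traits. Two modes:
#' `"zdiff"` holds z-scored differences from the sex-matched control (control
#' rows are exactly zero); `"absolute"` holds pooled male + female values
#' z-normalised per trait (each column has mean 0 and SD 1).
#'
#' @slot values numeric matrix.
#' @slot mode `"zdiff"` or `"absolute"`.
#' @slot rowInfo data.frame with `gene`, `sex`, `isControl` per row.
#' @exportClass ProfileMatrix
setClass("ProfileMatrix", representation(
  values = "matrix", mode = "character", rowInfo = "data.frame"))

setValidity("ProfileMatrix", function(object) {
  if (nrow(object@values) != nrow(object@rowInfo))
    return("rowInfo must describe every matrix row")
  if (!object@mode %in% c("zdiff", "absolute"))
    return("mode must be 'zdiff' or 'absolute'")
  TRUE
})

#' Centered-SVD PCA embedding of phenotype profiles
#'
#' @slot scores row scores (U * Sigma).
#' @slot loadings column loadings (V).
#' @slot varExplained explained-variance fractions, nonincreasing, sum 1.
#' @slot rowInfo data.frame describing the rows.
#' @exportClass PhenoEmbedding
setClass("PhenoEmbedding", representation(
  scores = "matrix", loadings = "matrix", varExplained = "numeric",
  rowInfo = "data.frame"))

setValidity("PhenoEmbedding", function(object) {
  v <- object@varExplained
  if (any(diff(v) > 1e-8)) return("explained variance must be nonincreasing")
  if (sum(v) > 1 + 1e-8) return("explained-variance fractions must sum to <= 1")
  TRUE
})
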
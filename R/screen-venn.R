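#' Venn triple of sex-resolved hits and its derived fractions
#'
#' From counts of male-only, female-only and shared hits, computes the
#' fractions printed on sex-specificity Venn diagrams: the fraction of each
#' sex's hits shared with the other sex, the sex-specific fractions, and
#' the fraction of all hit genes common to both sexes. All fractions follow
#' exactly from the integer triple.
#'
#' @param maleOnly,femaleOnly,shared nonnegative integer counts.
#' @return list with the counts and `femaleShared`, `maleShared`,
#'   `femaleSpecific`, `maleSpecific`, `common` fractions (NA where the
#'   relevant sex has zero hits), plus the same as rounded percentages
#'   (`*_pct`).
#' @export
#' @examples
#' vennTriple(89, 8, 38)$femaleShared   # 38/46
vennTriple <- function(maleOnly, femaleOnly, shared) {
  stopifnot(maleOnly >= 0, femaleOnly >= 0, shared >= 0)
  fTot <- femaleOnly + shared
  mTot <- maleOnly + shared
  fs <- if (fTot > 0) shared / fTot else NA_real_
  ms <- if (mTot > 0) shared / mTot else NA_real_
  common <- if (maleOnly + femaleOnly + shared > 0)
    shared / (maleOnly + femaleOnly + shared) else NA_real_
  out <- list(maleOnly = maleOnly, femaleOnly = femaleOnly, shared = shared,
              femaleShared = fs, maleShared = ms,
              femaleSpecific = if (fTot > 0) femaleOnly / fTot else NA_real_,
              maleSpecific = if (mTot > 0) maleOnly / mTot else NA_real_,
              common = common)
  pct <- lapply(out[c("femaleShared", "maleShared", "femaleSpecific",
                      "maleSpecific", "common")],
                function(x) if (is.na(x)) NA_real_ else round(100 * x))
  names(pct) <- paste0(names(pct), "_pct")
  c(out, pct)
}

#' Sex-specificity atlas across all traits
#'
#' For every trait, crosses the hit sets of the two sexes on the shared
#' gene universe into a Venn triple and reports the per-sex sex-specific
#' fraction (the proportion of that sex's hits seen in that sex only).
#' Traits where a sex has zero hits report NA, not 0.
#'
#' @param hits a [HitTable-class].
#' @return list with `venn` (data.frame, one row per trait with counts and
#'   fractions) and `atlas` (trait x sex matrix of sex-specific fractions).
#' @export
sexSpecificityAtlas <- function(hits) {
  tab <- hitCalls(hits)
  traits <- unique(tab$trait)
  rows <- lapply(traits, function(tr) {
    sub <- tab[tab$trait == tr, ]
    fHits <- unique(sub$gene[sub$sex == "female" & sub$hit])
    mHits <- unique(sub$gene[sub$sex == "male" & sub$hit])
    sh <- length(intersect(fHits, mHits))
    vt <- vennTriple(length(setdiff(mHits, fHits)),
                     length(setdiff(fHits, mHits)), sh)
    data.frame(trait = tr, maleOnly = vt$maleOnly,
               femaleOnly = vt$femaleOnly, shared = vt$shared,
               femaleShared = vt$femaleShared, maleShared = vt$maleShared,
               femaleSpecific = vt$femaleSpecific,
               maleSpecific = vt$maleSpecific, common = vt$common,
               femaleSpecific_pct = vt$femaleSpecific_pct,
               maleSpecific_pct = vt$maleSpecific_pct)
  })
  venn <- do.call(rbind, rows)
  atlas <- cbind(female = venn$femaleSpecific, male = venn$maleSpecific)
  rownames(atlas) <- venn$trait
  list(venn = venn, atlas = atlas)
}
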
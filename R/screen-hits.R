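#' Scale values so the pooled maximum is 1
#'
#' Per-assay display scaling: every value is divided by the maximum
#' observed value with both sexes pooled, so the largest value maps to
#' exactly 1.0 and ordering is preserved.
#'
#' @param x numeric vector.
#' @return scaled vector.
#' @export
#' @examples
#' scaleToMax(c(2, 4, 8))
scaleToMax <- function(x) {
  if (!length(x) || all(x == 0, na.rm = TRUE))
    stop("cannot scale an all-zero trait")
  m <- max(x, na.rm = TRUE)
  if (m <= 0) stop("pooled maximum must be positive")
  x / m
}

#' Per-genotype means from a tidy replicate-level phenotype table
#'
#' @param table tidy data.frame (`genotype`, `sex`, `trait`, `value`).
#' @return data.frame with one row per genotype x sex x trait and a `mean`
#'   column.
#' @export
phenotypeMeans <- function(table) {
  stopifnot(all(c("genotype", "sex", "trait", "value") %in% names(table)))
  agg <- stats::aggregate(value ~ genotype + sex + trait, data = table,
                          FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean"
  agg
}

#' Call screen hits by the +-1.5 SD z-score rule
#'
#' For each sex x trait, the knockdown means are compared with the control
#' mean on the scale of the standard deviation computed across the means of
#' all knockdowns (control excluded by default); a knockdown is a hit when
#' |z| is strictly greater than the cutoff. No multiple-testing correction
#' is applied — the fixed-SD cutoff is the screen's uniform definition of
#' an extreme phenotype.
#'
#' @param table tidy replicate-level data.frame (`genotype`, `sex`,
#'   `trait`, `value`); control rows carry `controlLabel` as genotype.
#' @param cutoff positive z cutoff (default 1.5).
#' @param controlLabel genotype label of the control rows.
#' @param minKnockdowns minimum knockdown count per sex x trait for a
#'   stable SD (guard; default 10).
#' @param includeControl include the control mean in the SD (off by
#'   default, matching the "across the means of all knockdowns" phrasing).
#' @return a [HitTable-class].
#' @export
callHits <- function(table, cutoff = 1.5, controlLabel = "control",
                     minKnockdowns = 10L, includeControl = FALSE) {
  stopifnot(cutoff > 0)
  mm <- phenotypeMeans(table)
  if (!any(mm$genotype == controlLabel))
    stop(sprintf("no control rows labelled '%s'", controlLabel))
  res <- list(); sds <- list(); k <- 0L
  for (tr in unique(mm$trait)) for (sx in unique(mm$sex)) {
    sub <- mm[mm$trait == tr & mm$sex == sx, ]
    ctl <- sub$mean[sub$genotype == controlLabel]
    if (length(ctl) != 1L)
      stop(sprintf("expected exactly one control mean for %s/%s", tr, sx))
    kd <- sub[sub$genotype != controlLabel, ]
    if (nrow(kd) < minKnockdowns)
      stop(sprintf("fewer than %d knockdowns for %s/%s",
                   minKnockdowns, tr, sx))
    s <- if (includeControl) sd(sub$mean) else sd(kd$mean)
    if (s == 0) stop(sprintf("degenerate trait %s/%s: SD is zero", tr, sx))
    z <- (kd$mean - ctl) / s
    k <- k + 1L
    res[[k]] <- data.frame(gene = kd$genotype, sex = sx, trait = tr,
                           mean = kd$mean, controlMean = ctl, z = z,
                           hit = abs(z) > cutoff, sign = sign(z))
    sds[[k]] <- data.frame(sex = sx, trait = tr, sd = s)
  }
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  new("HitTable", table = tab, cutoff = cutoff,
      traitSD = do.call(rbind, sds))
}
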
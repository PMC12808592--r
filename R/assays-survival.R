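#' Summarize interval-censored survival records
#'
#' Individual death times are imputed at the midpoint of the check interval
#' in which they occurred (the first interval starts at time 0); per-vial
#' median survival and per-genotype means of vial medians are returned
#' together with a survival-curve table.
#'
#' @param df data.frame with columns `vial`, `time_h`, `cumulative_dead`
#'   and optionally `genotype` (default `"all"`).
#' @param fliesPerVial expected terminal count; if given, each vial's final
#'   cumulative count is checked against it.
#' @return list with `deaths` (imputed death times per fly), `vials`
#'   (per-vial `median_h` and `n`), `genotypes` (mean of vial medians), and
#'   `curve` (per genotype x time fraction alive).
#' @export
#' @examples
#' rec <- simulateSurvivalData(0.05, seed = 1)
#' summarizeSurvival(rec)$vials
summarizeSurvival <- function(df, fliesPerVial = NULL) {
  stopifnot(all(c("vial", "time_h", "cumulative_dead") %in% names(df)))
  if (!"genotype" %in% names(df)) df$genotype <- "all"
  key <- interaction(df$genotype, df$vial, drop = TRUE)
  deaths <- list()
  for (k in levels(key)) {
    v <- df[key == k, ]
    v <- v[order(v$time_h), ]
    if (any(diff(v$cumulative_dead) < 0))
      stop(sprintf("non-monotone cumulative dead counts in vial '%s'", k))
    if (!is.null(fliesPerVial) &&
        tail(v$cumulative_dead, 1) != fliesPerVial)
      stop(sprintf("vial '%s' does not end at %d flies", k, fliesPerVial))
    newDead <- diff(c(0L, v$cumulative_dead))
    mids <- (c(0, head(v$time_h, -1)) + v$time_h) / 2
    if (sum(newDead))
      deaths[[k]] <- data.frame(genotype = v$genotype[1], vial = v$vial[1],
                                death_h = rep(mids, newDead))
  }
  deaths <- do.call(rbind, deaths)
  rownames(deaths) <- NULL
  vials <- do.call(rbind, lapply(
    split(deaths, interaction(deaths$genotype, deaths$vial, drop = TRUE)),
    function(d) data.frame(genotype = d$genotype[1], vial = d$vial[1],
                           median_h = median(d$death_h), n = nrow(d))))
  rownames(vials) <- NULL
  genotypes <- do.call(rbind, lapply(split(vials, vials$genotype),
    function(d) data.frame(genotype = d$genotype[1],
                           mean_median_h = mean(d$median_h),
                           nVials = nrow(d))))
  rownames(genotypes) <- NULL
  curve <- do.call(rbind, lapply(split(df, df$genotype), function(d) {
    tot <- sum(vapply(split(d, d$vial),
                      function(v) max(v$cumulative_dead), numeric(1)))
    tt <- sort(unique(d$time_h))
    alive <- vapply(tt, function(x)
      1 - sum(d$cumulative_dead[d$time_h == x]) / tot, numeric(1))
    data.frame(genotype = d$genotype[1], time_h = tt, fractionAlive = alive)
  }))
  rownames(curve) <- NULL
  list(deaths = deaths, vials = vials, genotypes = genotypes, curve = curve)
}

#' Compare genotype survival by one-way ANOVA with Tukey post hoc tests
#'
#' Operates on per-vial median survival as the replicate unit.
#'
#' @param vials data.frame with `genotype` and `median_h` columns, as from
#'   [summarizeSurvival()].
#' @return list with `anova` (F, df, p) and `tukey` (data.frame of pairwise
#'   differences and adjusted p-values).
#' @export
compareSurvival <- function(vials) {
  stopifnot(all(c("genotype", "median_h") %in% names(vials)))
  if (length(unique(vials$genotype)) < 2L)
    stop("need at least 2 genotypes")
  fit <- aov(median_h ~ genotype, data = vials)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$genotype
  list(anova = list(F = an[1, "F value"],
                    df = unname(an[, "Df"]), p = an[1, "Pr(>F)"]),
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p = tk[, "p adj"], row.names = NULL))
}
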
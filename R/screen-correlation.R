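#' Cross-sex concordance of knockdown effects for one trait
#'
#' Plots-ready reduction of the female-vs-male effect relationship:
#' ordinary least-squares fit of the male effect on the female effect
#' (slope, R^2, slope p-value, 95% confidence band) and a per-gene class:
#' `discordant` when the two sexes' effects have opposite signs and both
#' |z| exceed the hit cutoff; `sex_biased` when the point falls outside the
#' 95% confidence band; `concordant` otherwise.
#'
#' @param hits a [HitTable-class].
#' @param trait trait to analyse.
#' @return list with `fit` (slope, intercept, r2, p), `genes` (data.frame
#'   with per-gene female/male z and class), `band` (confidence band over
#'   the female-effect range).
#' @export
concordanceScatter <- function(hits, trait) {
  tab <- hitCalls(hits)
  sub <- tab[tab$trait == trait, ]
  if (!nrow(sub)) stop(sprintf("trait '%s' not present", trait))
  f <- sub[sub$sex == "female", c("gene", "z")]
  m <- sub[sub$sex == "male", c("gene", "z")]
  mg <- merge(f, m, by = "gene", suffixes = c("F", "M"))
  if (nrow(mg) < 3L) stop("need paired effects for >= 3 genes")
  if (var(mg$zF) == 0) stop("constant female effects: cannot fit")
  fit <- lm(zM ~ zF, data = mg)
  sm <- summary(fit)
  cb <- predict(fit, interval = "confidence", level = 0.95)
  cut <- hitCutoff(hits)
  cls <- ifelse(sign(mg$zF) * sign(mg$zM) < 0 &
                  abs(mg$zF) > cut & abs(mg$zM) > cut, "discordant",
                ifelse(mg$zM < cb[, "lwr"] | mg$zM > cb[, "upr"],
                       "sex_biased", "concordant"))
  xo <- order(mg$zF)
  list(fit = list(slope = unname(coef(fit)[2]),
                  intercept = unname(coef(fit)[1]),
                  r2 = sm$r.squared,
                  p = sm$coefficients["zF", "Pr(>|t|)"]),
       genes = data.frame(gene = mg$gene, zFemale = mg$zF, zMale = mg$zM,
                          class = cls),
       band = data.frame(zFemale = mg$zF[xo], fitted = cb[xo, "fit"],
                         lwr = cb[xo, "lwr"], upr = cb[xo, "upr"]))
}

#' Trait-trait correlation across knockdowns, per sex
#'
#' For each sex, ordinary least-squares fit of trait `y` on trait `x`
#' across knockdown means, reporting the slope m, coefficient of
#' determination R^2 and the two-sided p-value that the slope is zero,
#' with knockdowns outside the 95% confidence band flagged as outliers.
#'
#' @param table tidy replicate-level phenotype table.
#' @param xTrait,yTrait trait names.
#' @param controlLabel control genotype label (excluded from the fit).
#' @return data.frame with one row per sex: `sex`, `slope`, `intercept`,
#'   `r2`, `p`, `n`, `outliers` (comma-separated gene list).
#' @export
traitCorrelation <- function(table, xTrait, yTrait,
                             controlLabel = "control") {
  mm <- phenotypeMeans(table)
  mm <- mm[mm$genotype != controlLabel, ]
  out <- lapply(unique(mm$sex), function(sx) {
    x <- mm[mm$sex == sx & mm$trait == xTrait, c("genotype", "mean")]
    y <- mm[mm$sex == sx & mm$trait == yTrait, c("genotype", "mean")]
    d <- merge(x, y, by = "genotype", suffixes = c("X", "Y"))
    if (nrow(d) < 3L) stop("need >= 3 paired knockdown values")
    if (var(d$meanX) == 0) stop("constant x trait: cannot fit")
    fit <- lm(meanY ~ meanX, data = d)
    sm <- summary(fit)
    cb <- predict(fit, interval = "confidence", level = 0.95)
    outl <- d$genotype[d$meanY < cb[, "lwr"] | d$meanY > cb[, "upr"]]
    data.frame(sex = sx, slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]), r2 = sm$r.squared,
               p = sm$coefficients["meanX", "Pr(>|t|)"], n = nrow(d),
               outliers = paste(outl, collapse = ","))
  })
  do.call(rbind, out)
}

#' Pairwise Spearman correlation between phenotype profiles
#'
#' Rank correlation with average ranks for ties, pairwise-complete handling
#' of missing traits, and a two-sided p-value from the t approximation;
#' pairs with fewer than `minShared` complete trait pairs are reported
#' missing.
#'
#' @param profiles numeric matrix, rows = genes (profiles), columns =
#'   traits.
#' @param minShared minimum complete pairs per correlation.
#' @return list of matrices `r` and `p`.
#' @export
pairwiseSpearman <- function(profiles, minShared = 5L) {
  stopifnot(is.matrix(profiles))
  n <- nrow(profiles)
  r <- p <- matrix(NA_real_, n, n,
                   dimnames = list(rownames(profiles), rownames(profiles)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)[-seq_len(i)]) {
    ok <- !is.na(profiles[i, ]) & !is.na(profiles[j, ])
    m <- sum(ok)
    if (m < minShared) next
    rs <- cor(rank(profiles[i, ok]), rank(profiles[j, ok]))
    r[i, j] <- r[j, i] <- rs
    p[i, j] <- p[j, i] <- if (abs(rs) >= 1) 0 else {
      tt <- rs * sqrt((m - 2) / (1 - rs^2))
      2 * pt(-abs(tt), m - 2)
    }
  }
  list(r = r, p = p)
}
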
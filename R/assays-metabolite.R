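#' Fit a colorimetric standard curve
#'
#' Ordinary least-squares fit of absorbance on concentration; requires at
#' least 3 points and R^2 >= 0.95, the quality gate for BSA / glycerol /
#' glucose standards.
#'
#' @param concentration known standard concentrations.
#' @param absorbance measured absorbances.
#' @param minR2 minimum acceptable R^2.
#' @return list with `slope`, `intercept`, `r2`.
#' @export
fitStandardCurve <- function(concentration, absorbance, minR2 = 0.95) {
  if (length(concentration) < 3L)
    stop("standard curve needs >= 3 points")
  fit <- lm(absorbance ~ concentration)
  r2 <- summary(fit)$r.squared
  if (is.na(r2) || r2 < minR2)
    stop(sprintf("standard curve R^2 = %.3f below %.2f", r2, minR2))
  sl <- unname(coef(fit)[2])
  if (sl <= 0) stop("standard curve slope must be positive")
  list(slope = sl, intercept = unname(coef(fit)[1]), r2 = r2)
}

#' Quantify a metabolite measurement from absorbance
#'
#' Inverts the standard curve (`amount = (absorbance - intercept) / slope`)
#' and normalizes either to protein content (screen convention, robust to
#' homogenization variability) or to fly number (validation convention,
#' which preserves true sex differences since females contain more
#' protein). Absorbances below the curve intercept are clamped to zero
#' with a warning flag rather than reported negative.
#'
#' @param absorbance raw absorbance value(s).
#' @param curve list with `slope` and `intercept` (see
#'   [fitStandardCurve()]).
#' @param normalization `"protein"` or `"per_fly"`.
#' @param protein protein amount of the homogenate (same units as the
#'   curve), required for protein normalization.
#' @param nFlies number of flies in the homogenate, required for per-fly
#'   normalization.
#' @return data.frame with `amount` (raw curve inversion), `normalized`,
#'   and `clamped` (logical).
#' @export
#' @examples
#' quantifyMetabolite(0.5, list(slope = 2, intercept = 0.1),
#'                    normalization = "per_fly", nFlies = 4)
quantifyMetabolite <- function(absorbance, curve,
                               normalization = c("protein", "per_fly"),
                               protein = NULL, nFlies = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(absorbance), curve$slope > 0)
  amount <- (absorbance - curve$intercept) / curve$slope
  clamped <- amount < 0
  if (any(clamped)) {
    warning("absorbance below blank; amount clamped to 0")
    amount[clamped] <- 0
  }
  denom <- if (normalization == "protein") {
    if (is.null(protein) || any(protein <= 0))
      stop("protein normalization needs positive protein amounts")
    protein
  } else {
    if (is.null(nFlies) || any(nFlies < 1))
      stop("per-fly normalization needs nFlies >= 1")
    nFlies
  }
  data.frame(amount = amount, normalized = amount / denom,
             clamped = clamped)
}

#' Starvation utilization of a metabolite
#'
#' Utilization is the drop from the fed to the starved state,
#' `mean(fed) - mean(starved)`, an independent measure of energy
#' mobilization; the fractional mode reports `(fed - starved) / fed`.
#' The confidence interval is a percentile bootstrap over replicates.
#'
#' @param fed,starved numeric replicate vectors for the matched groups.
#' @param mode `"absolute"` or `"fractional"`.
#' @param nBoot bootstrap resamples.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return list with `utilization`, `ciLow`, `ciHigh`, `mode`.
#' @export
starvationDelta <- function(fed, starved, mode = c("absolute", "fractional"),
                            nBoot = 1000L, conf = 0.95, seed = 1L) {
  mode <- match.arg(mode)
  if (!length(fed) || !length(starved))
    stop("both fed and starved replicates are required")
  stat <- function(f, s) {
    d <- mean(f) - mean(s)
    if (mode == "fractional") d / mean(f) else d
  }
  est <- stat(fed, starved)
  bs <- withSeed(seed, vapply(seq_len(nBoot), function(b)
    stat(sample(fed, replace = TRUE), sample(starved, replace = TRUE)),
    numeric(1)))
  a <- (1 - conf) / 2
  ci <- quantile(bs, c(a, 1 - a), na.rm = TRUE)
  list(utilization = est, ciLow = unname(ci[1]), ciHigh = unname(ci[2]),
       mode = mode)
}
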
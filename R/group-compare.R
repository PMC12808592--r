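#' Distribution function of the studentized maximum modulus
#'
#' `P(max_i |T_i| <= q)` for `r` independent standard normals studentized
#' by a shared chi-squared scale on `df` degrees of freedom, computed by
#' numerical integration over the scale density. Used for Dunnett T3
#' all-pairs comparisons.
#'
#' @param q quantile (nonnegative).
#' @param r number of comparisons.
#' @param df degrees of freedom.
#' @return probability.
#' @export
pSMM <- function(q, r, df) {
  stopifnot(q >= 0, r >= 1, df > 0)
  if (!is.finite(df) || df > 2000)
    return((2 * pnorm(q) - 1)^r)
  # density of s = sqrt(chi2_df / df)
  fs <- function(s) 2 * s * df * dchisq(df * s^2, df)
  f <- function(s) (2 * pnorm(q * s) - 1)^r * fs(s)
  integrate(f, 0, Inf, rel.tol = 1e-9)$value
}

#' All-pairs Dunnett T3 comparisons
#'
#' Welch-type pairwise t statistics with Welch-Satterthwaite degrees of
#' freedom, referred to the studentized maximum modulus distribution with
#' the number of comparisons as its extent; appropriate when group
#' variances are unequal.
#'
#' @param values numeric vector of observations.
#' @param groups factor/character of the same length.
#' @return data.frame with one row per pair: `group1`, `group2`,
#'   `estimate`, `t`, `df`, `p`.
#' @export
dunnettT3 <- function(values, groups) {
  groups <- as.character(groups)
  gs <- unique(groups)
  if (length(gs) < 2L) stop("need at least 2 groups")
  m <- vapply(gs, function(g) mean(values[groups == g]), numeric(1))
  v <- vapply(gs, function(g) var(values[groups == g]), numeric(1))
  n <- vapply(gs, function(g) sum(groups == g), numeric(1))
  if (any(n < 2)) stop("every group needs >= 2 values")
  pairs <- utils::combn(seq_along(gs), 2)
  r <- ncol(pairs)
  out <- lapply(seq_len(r), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se2 <- v[i] / n[i] + v[j] / n[j]
    if (se2 == 0) {
      tt <- if (m[i] == m[j]) 0 else Inf
      df <- n[i] + n[j] - 2
    } else {
      tt <- (m[i] - m[j]) / sqrt(se2)
      df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                       (v[j] / n[j])^2 / (n[j] - 1))
    }
    p <- if (is.infinite(tt)) 0 else 1 - pSMM(abs(tt), r, df)
    data.frame(group1 = gs[i], group2 = gs[j], estimate = m[i] - m[j],
               t = tt, df = df, p = p)
  })
  do.call(rbind, out)
}

#' Omnibus and pairwise comparison of per-gut group values
#'
#' Welch's (unequal-variance) one-way ANOVA as the omnibus test, followed by
#' Dunnett T3 all-pairs comparisons — the convention for comparing gut
#' length, cell counts and densities across sex/genotype/mating groups.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list with `omnibus` (statistic, df, p) and `pairwise`
#'   (a [dunnettT3()] table).
#' @export
#' @examples
#' set.seed(1)
#' groupCompare(c(rnorm(5), rnorm(5, 2)), rep(c("a", "b"), each = 5))
groupCompare <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  gs <- unique(groups)
  if (length(gs) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 3L)) stop("every group needs >= 3 values")
  vs <- vapply(gs, function(g) var(values[groups == g]), numeric(1))
  if (all(vs == 0)) stop("zero within-group variance in all groups")
  ow <- oneway.test(values ~ factor(groups), var.equal = FALSE)
  list(omnibus = list(statistic = unname(ow$statistic),
                      df = unname(ow$parameter), p = ow$p.value),
       pairwise = dunnettT3(values, groups))
}
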
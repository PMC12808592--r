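# internal helpers

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Holm-Sidak step-down adjustment for m two-sided p-values.

#' Holm-Sidak step-down multiple-testing adjustment
#'
#' Orders the p-values, applies the Sidak correction with a step-down
#' multiplicity (`1 - (1 - p_(i))^(m - i + 1)`), and enforces monotonicity,
#' the convention used for per-decile sex comparisons of regional cell
#' counts.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holmSidak <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p, na.last = TRUE)
  ps <- p[ord]
  k <- sum(!is.na(ps))
  adj <- rep(NA_real_, m)
  if (k > 0L) {
    a <- 1 - (1 - ps[seq_len(k)])^(k - seq_len(k) + 1L)
    adj[seq_len(k)] <- pmin(1, cummax(a))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}
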
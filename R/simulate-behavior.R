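#' Simulate a minute-binned beam-crossing activity series
#'
#' Produces a 24 h (1440-bin) DAMS-style count series. Declared sleep bouts
#' are rendered as runs of zero counts; awake minutes carry Poisson counts,
#' post-processed so that no awake zero-run reaches the 5-minute sleep
#' threshold or touches a planted bout (which would otherwise extend it).
#' The ground truth is the total planted bout time among bouts of at least
#' 5 minutes, the scoring rule's threshold.
#'
#' @param sleepBouts two-column matrix (start, end) of half-open minute
#'   intervals `[start, end)` within `[0, 1440)`, non-overlapping.
#' @param meanActivity Poisson mean of awake beam crossings per minute.
#' @param seed integer RNG seed.
#' @return list with `counts` (integer, length 1440) and `truth`
#'   (list: `sleepMinutes`, `bouts`).
#' @export
#' @examples
#' sim <- simulateActivitySeries(cbind(600, 700), seed = 1)
#' sim$truth$sleepMinutes
simulateActivitySeries <- function(sleepBouts = NULL, meanActivity = 2,
                                   seed = 1L) {
  if (is.null(sleepBouts)) sleepBouts <- matrix(numeric(0), 0, 2)
  sleepBouts <- matrix(as.numeric(sleepBouts), ncol = 2)
  if (nrow(sleepBouts)) {
    if (any(sleepBouts[, 1] < 0) || any(sleepBouts[, 2] > 1440) ||
        any(sleepBouts[, 2] <= sleepBouts[, 1]))
      stop("bouts must be nonempty intervals within [0, 1440)")
    o <- order(sleepBouts[, 1])
    sleepBouts <- sleepBouts[o, , drop = FALSE]
    if (nrow(sleepBouts) > 1L &&
        any(sleepBouts[-1, 1] < sleepBouts[-nrow(sleepBouts), 2]))
      stop("sleep bouts must not overlap")
  }
  withSeed(seed, {
    counts <- rpois(1440, meanActivity)
    inBout <- rep(FALSE, 1440)
    for (i in seq_len(nrow(sleepBouts))) {
      mins <- (floor(sleepBouts[i, 1]) + 1L):ceiling(sleepBouts[i, 2])
      inBout[mins] <- TRUE
    }
    counts[inBout] <- 0L
    # awake minutes adjacent to a bout must register activity, and awake
    # zero-runs are broken before they reach 5 minutes
    adj <- which(!inBout &
                   (c(FALSE, inBout[-1440]) | c(inBout[-1], FALSE)))
    counts[adj] <- pmax(1L, counts[adj])
    run <- 0L
    for (m in seq_len(1440)) {
      if (inBout[m]) { run <- 0L; next }
      if (counts[m] == 0L) {
        run <- run + 1L
        if (run >= 4L) { counts[m] <- 1L + rpois(1, meanActivity); run <- 0L }
      } else run <- 0L
    }
    lens <- sleepBouts[, 2] - sleepBouts[, 1]
    list(counts = as.integer(counts),
         truth = list(sleepMinutes = sum(lens[lens >= 5]),
                      bouts = sleepBouts))
  })
}

#' Simulate interval-censored survival counts
#'
#' Death times are exponential with the given per-hour hazard; each vial is
#' checked at a fixed interval (6-8 h in the emulated protocol) until every
#' fly has died, and the cumulative dead count is recorded at each check.
#'
#' @param hazard per-hour death hazard (positive).
#' @param nVials number of replicate vials.
#' @param fliesPerVial flies per vial.
#' @param checkIntervalH hours between checks, in [6, 8].
#' @param seed integer RNG seed.
#' @return data.frame with columns `vial`, `time_h`, `cumulative_dead`
#'   (monotone nondecreasing per vial; terminal count = `fliesPerVial`).
#' @export
#' @examples
#' simulateSurvivalData(0.05, nVials = 3, seed = 2)
simulateSurvivalData <- function(hazard, nVials = 3L, fliesPerVial = 20L,
                                 checkIntervalH = 7, seed = 1L) {
  stopifnot(hazard > 0, nVials >= 1, fliesPerVial >= 1)
  if (checkIntervalH < 6 || checkIntervalH > 8)
    stop("checkIntervalH must lie in [6, 8] hours")
  withSeed(seed, {
    out <- lapply(seq_len(nVials), function(v) {
      d <- rexp(fliesPerVial, hazard)
      checks <- seq(checkIntervalH, by = checkIntervalH,
                    length.out = ceiling(max(d) / checkIntervalH))
      data.frame(vial = v, time_h = checks,
                 cumulative_dead = vapply(checks, function(tt)
                   sum(d <= tt), integer(1)))
    })
    do.call(rbind, out)
  })
}
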
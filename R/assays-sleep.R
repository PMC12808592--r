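#' Score sleep from a minute-binned activity series
#'
#' Sleep is the total length of maximal runs of at least 5 consecutive
#' minutes without beam crossings. Each day of a 12:12 light:dark cycle is
#' split into a day phase (`[lightsOn, lightsOn + 720)` minutes, ZT0-ZT12)
#' and a night phase; a run crossing the phase boundary contributes its
#' minutes to both phases, split at the boundary.
#'
#' @param counts nonnegative integer vector of beam crossings per minute;
#'   the length must be a positive multiple of 1440.
#' @param lightsOnMinute minute-of-day (0-1439) of lights-on for the first
#'   recorded minute; the recording is assumed to start at lights-on by
#'   default (`0`).
#' @param threshold minimum run length scored as sleep (minutes).
#' @return data.frame with one row per recorded day: `day`, `daySleep`,
#'   `nightSleep`, `totalSleep` (minutes), `dayActivity`, `nightActivity`
#'   (summed counts).
#' @export
#' @examples
#' scoreSleep(rep(0L, 1440))            # asleep all day: 720 + 720
#' scoreSleep(rep(c(0L, 0L, 0L, 0L, 1L), 288))  # 4-min gaps: no sleep
scoreSleep <- function(counts, lightsOnMinute = 0L, threshold = 5L) {
  if (length(counts) < 1440L || length(counts) %% 1440L != 0L)
    stop("activity series must cover whole days (length multiple of 1440)")
  if (any(counts < 0)) stop("counts must be nonnegative")
  nDays <- length(counts) %/% 1440L

  asleep <- rep(FALSE, length(counts))
  r <- rle(counts == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths >= threshold))
    asleep[starts[i]:ends[i]] <- TRUE

  minuteOfDay <- (seq_along(counts) - 1L + lightsOnMinute) %% 1440L
  isDay <- minuteOfDay < 720L
  dayIndex <- (seq_along(counts) - 1L) %/% 1440L + 1L

  out <- lapply(seq_len(nDays), function(d) {
    sel <- dayIndex == d
    data.frame(day = d,
               daySleep = sum(asleep[sel & isDay]),
               nightSleep = sum(asleep[sel & !isDay]),
               totalSleep = sum(asleep[sel]),
               dayActivity = sum(counts[sel & isDay]),
               nightActivity = sum(counts[sel & !isDay]))
  })
  do.call(rbind, out)
}
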
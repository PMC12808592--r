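#' Feeding-event features from a FLIC contact-event list
#'
#' Starts from detected food-contact events (start/end seconds); events
#' separated by less than `minEventGap` seconds are merged into one meal.
#' Returns the meal count and the total feeding duration, where a merged
#' meal's duration spans from its first contact to its last.
#'
#' @param events data.frame with numeric `start` and `end` columns
#'   (seconds), ordered and non-overlapping.
#' @param minEventGap merge gap in seconds (0 = no merging).
#' @return list with `nEvents`, `totalDuration`, and `merged` (the merged
#'   event table).
#' @export
#' @examples
#' flicFeatures(data.frame(start = c(0, 3), end = c(2, 5)), minEventGap = 2)
flicFeatures <- function(events, minEventGap = 5) {
  stopifnot(is.data.frame(events), all(c("start", "end") %in% names(events)))
  if (!nrow(events))
    return(list(nEvents = 0L, totalDuration = 0,
                merged = data.frame(start = numeric(0), end = numeric(0))))
  if (any(events$end < events$start))
    stop("negative event durations in the FLIC record")
  o <- order(events$start)
  events <- events[o, ]
  if (nrow(events) > 1L &&
      any(events$start[-1] < events$end[-nrow(events)]))
    stop("overlapping events in the FLIC record")
  st <- events$start[1]; en <- events$end[1]
  ms <- numeric(0); me <- numeric(0)
  for (i in seq_len(nrow(events))[-1]) {
    if (events$start[i] - en < minEventGap) {
      en <- events$end[i]
    } else {
      ms <- c(ms, st); me <- c(me, en)
      st <- events$start[i]; en <- events$end[i]
    }
  }
  ms <- c(ms, st); me <- c(me, en)
  list(nEvents = length(ms), totalDuration = sum(me - ms),
       merged = data.frame(start = ms, end = me))
}

#' Two-dye choice-assay consumption and preference
#'
#' Inverts the per-dye standard curves to obtain the consumed amounts of
#' the sucrose diet (amaranth, 520 nm) and the yeast diet (erioglaucine,
#' 629 nm), and reports the yeast preference index
#' `yeast / (yeast + sucrose)`; the index is missing (NA) when both
#' consumptions are zero.
#'
#' @param a520,a629 absorbances at 520 and 629 nm.
#' @param curveSucrose,curveYeast standard-curve lists with `slope` and
#'   `intercept`.
#' @return data.frame with `sucrose`, `yeast`, `preference`.
#' @export
#' @examples
#' cv <- list(slope = 1, intercept = 0)
#' dyeChoice(1, 3, cv, cv)$preference   # 0.75
dyeChoice <- function(a520, a629, curveSucrose, curveYeast) {
  stopifnot(curveSucrose$slope > 0, curveYeast$slope > 0)
  suc <- pmax(0, (a520 - curveSucrose$intercept) / curveSucrose$slope)
  yst <- pmax(0, (a629 - curveYeast$intercept) / curveYeast$slope)
  pref <- ifelse(suc + yst > 0, yst / (suc + yst), NA_real_)
  data.frame(sucrose = suc, yeast = yst, preference = pref)
}
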
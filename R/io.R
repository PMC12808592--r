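#' Read a tidy phenotype table (CSV or TSV)
#'
#' Validates the screen-table schema: required columns `genotype`, `sex`,
#' `trait`, `replicate`, `value`; sex labels restricted to male/female;
#' exactly one control genotype per sex x trait. Schema violations name
#' the offending rows or traits; nothing is silently coerced.
#'
#' @param path file path; the dialect is sniffed from the header line.
#' @param controlLabel genotype label identifying control rows.
#' @return validated data.frame.
#' @export
readPhenotypeTable <- function(path, controlLabel = "control") {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("genotype", "sex", "trait", "replicate", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("phenotype table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  bad <- which(!df$sex %in% c("male", "female"))
  if (length(bad))
    stop(sprintf("unknown sex label(s) at row(s): %s",
                 paste(head(bad, 5), collapse = ", ")))
  if (!is.numeric(df$value))
    stop("value column must be numeric")
  for (tr in unique(df$trait)) for (sx in unique(df$sex)) {
    sub <- df[df$trait == tr & df$sex == sx, ]
    if (!any(sub$genotype == controlLabel))
      stop(sprintf("no control rows for trait '%s' (%s)", tr, sx))
  }
  df
}

#' Write a tidy phenotype table as CSV
#'
#' Numeric values are written with 17 significant digits so that a
#' write/read round trip reproduces them bit-exactly.
#'
#' @param table data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePhenotypeTable <- function(table, path) {
  out <- table
  if ("value" %in% names(out) && is.numeric(out$value))
    out$value <- formatC(out$value, digits = 17, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

monthAbb <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
              "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

#' Write minute-binned counts in the TriKinetics DAMS monitor dialect
#'
#' Tab-delimited rows: reading index, date (`d mmm yy`), time (`HH:MM:SS`),
#' monitor status, five extra status fields, the light indicator, then 32
#' per-channel counts — one row per minute.
#'
#' @param counts integer matrix (minutes x 32 channels) or a vector (placed
#'   in channel 1, other channels zero).
#' @param path output path.
#' @param startMinute minute of day of the first row (default 480 = 08:00).
#' @param lightsOnMinute minute of day of lights-on, for the light column.
#' @return invisibly, the path.
#' @export
writeDams <- function(counts, path, startMinute = 480L,
                      lightsOnMinute = 480L) {
  if (is.vector(counts)) {
    m <- matrix(0L, length(counts), 32L)
    m[, 1] <- as.integer(counts)
    counts <- m
  }
  stopifnot(is.matrix(counts), ncol(counts) == 32L)
  n <- nrow(counts)
  minute <- (startMinute + seq_len(n) - 1L)
  day <- minute %/% 1440L
  mod <- minute %% 1440L
  date <- sprintf("%d %s %02d", 1L + day, monthAbb[1], 24L)
  time <- sprintf("%02d:%02d:00", mod %/% 60L, mod %% 60L)
  light <- as.integer(((mod - lightsOnMinute) %% 1440L) < 720L)
  rows <- paste(seq_len(n), date, time, 1L, 0L, 0L, 0L, 0L, 0L, light,
                apply(counts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Read a TriKinetics DAMS monitor file
#'
#' @param path monitor file path.
#' @return list with `counts` (minutes x 32 integer matrix), `minuteOfDay`
#'   (per row), `light` (per row), `index` (reading index).
#' @export
readDams <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  len <- lengths(parts)
  if (any(len != 42L))
    stop(sprintf("ragged DAMS row(s) at line(s): %s",
                 paste(head(which(len != 42L), 5), collapse = ", ")))
  tm <- vapply(parts, `[[`, character(1), 3L)
  hms <- do.call(rbind, strsplit(tm, ":", fixed = TRUE))
  minuteOfDay <- as.integer(hms[, 1]) * 60L + as.integer(hms[, 2])
  date <- vapply(parts, `[[`, character(1), 2L)
  dayNum <- as.integer(sub("^(\\d+) .*", "\\1", date))
  absMinute <- dayNum * 1440L + minuteOfDay
  if (any(diff(absMinute) <= 0))
    stop(sprintf("out-of-order timestamps at line %d",
                 which(diff(absMinute) <= 0)[1] + 1L))
  counts <- t(vapply(parts, function(p) as.integer(p[11:42]),
                     integer(32)))
  emptyCh <- which(colSums(counts) == 0L)
  list(counts = counts, minuteOfDay = minuteOfDay,
       light = as.integer(vapply(parts, `[[`, character(1), 10L)),
       index = as.integer(vapply(parts, `[[`, character(1), 1L)),
       emptyChannels = emptyCh)
}
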
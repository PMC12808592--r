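# Shared oracles and fixture builders, independent of the implementations
# they check.

# Greedy one-to-one matching of detected centroids to true coordinates
# within a radius; returns recall and precision.
matchCentroids <- function(centroids, truth, radius = 5) {
  used <- rep(FALSE, nrow(centroids))
  hit <- 0L
  for (i in seq_len(nrow(truth))) {
    d2 <- (centroids$x - truth$x[i])^2 + (centroids$y - truth$y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= radius^2) {
      used[j] <- TRUE
      hit <- hit + 1L
    }
  }
  c(recall = hit / nrow(truth),
    precision = if (nrow(centroids)) hit / nrow(centroids) else NA_real_)
}

# Brute-force sleep scorer: walks every minute and extends a candidate
# zero-run with explicit loops; no rle, no vectorized tricks.
bruteForceSleep <- function(counts, lightsOnMinute = 0L, threshold = 5L) {
  n <- length(counts)
  asleep <- rep(FALSE, n)
  i <- 1L
  while (i <= n) {
    if (counts[i] == 0L) {
      j <- i
      while (j < n && counts[j + 1L] == 0L) j <- j + 1L
      if (j - i + 1L >= threshold) asleep[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  day <- ((seq_len(n) - 1L + lightsOnMinute) %% 1440L) < 720L
  c(daySleep = sum(asleep & day), nightSleep = sum(asleep & !day))
}

# Minimal valid GutQuantification carrying prescribed per-decile GFP counts
# (all cells flagged GFP+), for count-level statistics without imaging.
countQuant <- function(lengthPx, gfpCounts, sex) {
  dec <- rep(0:9, gfpCounts)
  cells <- data.frame(x = 0, y = 0, t = (dec + 0.5) / 10, decile = dec,
                      gfp = TRUE)
  new("GutQuantification", lengthPx = lengthPx, cells = cells,
      decileCountsTotal = as.integer(gfpCounts),
      decileCountsGFP = as.integer(gfpCounts),
      sex = sex, genotype = "control", mating = "mated")
}

# Poisson count-level cohort with equal per-length density in both sexes
# and an optional multiplicative female enrichment of selected deciles.
countCohort <- function(nPerSex = 10, maleLen = 1000, ratio = 1.4,
                        densityPerPx = 0.15, enrichDeciles = integer(0),
                        fold = 1) {
  mu <- function(len, enrich) {
    base <- rep(len / 10 * densityPerPx, 10)  # per-decile expected count
    if (enrich && length(enrichDeciles))
      base[enrichDeciles + 1] <- base[enrichDeciles + 1] * fold
    base
  }
  fem <- lapply(seq_len(nPerSex), function(i)
    countQuant(maleLen * ratio, rpois(10, mu(maleLen * ratio, TRUE)),
               "female"))
  mal <- lapply(seq_len(nPerSex), function(i)
    countQuant(maleLen, rpois(10, mu(maleLen, FALSE)), "male"))
  list(female = fem, male = mal)
}

# Rand index between two partitions.
randIndex <- function(a, b) {
  n <- length(a)
  agree <- 0L
  tot <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + 1L
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  agree / tot
}

# Small replicate-level table with exact genotype means (replicates all
# equal to the mean), for hand-computed z-score checks.
meansTable <- function(means, control, trait = "t1", sex = "female",
                       nRep = 2) {
  genos <- c(names(means), "control")
  vals <- c(means, control = control)
  do.call(rbind, lapply(genos, function(g)
    data.frame(genotype = g, sex = sex, trait = trait,
               replicate = seq_len(nRep), value = vals[[g]])))
}
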
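test_that("sleep scoring matches hand-enumerated zero runs", {
  # all-zero day: 720 day + 720 night
  s <- scoreSleep(rep(0L, 1440))
  expect_equal(s$daySleep, 720)
  expect_equal(s$nightSleep, 720)
  # crossings every 4 minutes: no run reaches 5 minutes
  s4 <- scoreSleep(rep(c(1L, 0L, 0L, 0L, 0L), 288))
  expect_equal(s4$totalSleep, 0L)
  # active day except one 60-min window with crossings only at its
  # minutes 0 and 30: two maximal 29-min zero runs -> 58 sleep minutes
  x <- rep(1L, 1440)
  x[241:300] <- 0L
  x[241] <- 1L
  x[271] <- 1L
  expect_equal(scoreSleep(x)$daySleep, 58)
  # runs crossing the day/night boundary split at the boundary
  xb <- rep(1L, 1440)
  xb[711:730] <- 0L
  sb <- scoreSleep(xb)
  expect_equal(sb$daySleep, 10)
  expect_equal(sb$nightSleep, 10)
  expect_error(scoreSleep(rep(0L, 100)), "1440")
})

test_that("sleep scoring equals the brute-force oracle on random series", {
  set.seed(14)
  for (i in 1:200) {
    counts <- rbinom(1440, 3, 0.35)
    ours <- scoreSleep(counts)
    oracle <- bruteForceSleep(counts)
    expect_identical(c(daySleep = ours$daySleep,
                       nightSleep = ours$nightSleep), oracle)
  }
})

test_that("survival medians follow midpoint imputation", {
  # all 20 flies dead at the first 6 h check: median at the 3 h midpoint
  d1 <- data.frame(vial = 1, time_h = 6, cumulative_dead = 20L)
  expect_equal(summarizeSurvival(d1)$vials$median_h, 3)
  # 10 deaths in (24, 30] and 10 in (30, 36]: even-n median (27+33)/2
  d2 <- data.frame(vial = 1, time_h = c(6, 12, 18, 24, 30, 36),
                   cumulative_dead = c(0L, 0L, 0L, 0L, 10L, 20L))
  expect_equal(summarizeSurvival(d2)$vials$median_h, 30)
  # non-monotone counts are a data-integrity error naming the vial
  d3 <- data.frame(vial = 7, time_h = c(6, 12),
                   cumulative_dead = c(5L, 3L))
  expect_error(summarizeSurvival(d3), "vial.*7")
})

test_that("identical genotypes yield Tukey p of 1", {
  # three vials with different death patterns, repeated identically in
  # two genotypes: within-genotype variance > 0, between = 0
  base <- data.frame(vial = rep(1:3, each = 2),
                     time_h = rep(c(6, 12), 3),
                     cumulative_dead = c(8L, 20L, 12L, 20L, 10L, 20L))
  a <- base; a$genotype <- "a"
  b <- base; b$vial <- b$vial + 10; b$genotype <- "b"
  s <- summarizeSurvival(rbind(a, b), fliesPerVial = 20)
  expect_identical(sort(s$vials$median_h[s$vials$genotype == "a"]),
                   sort(s$vials$median_h[s$vials$genotype == "b"]))
  cmp <- compareSurvival(s$vials)
  expect_gt(cmp$tukey$p, 0.99)
})

test_that("metabolite quantification inverts the standard curve", {
  cv <- list(slope = 2, intercept = 0.1)
  # absorbance at the intercept reads zero
  expect_equal(quantifyMetabolite(0.1, cv, "per_fly", nFlies = 4)$amount, 0)
  # worked example: (0.5 - 0.1) / 2 / 4 flies = 0.05 per fly
  q <- quantifyMetabolite(0.5, cv, "per_fly", nFlies = 4)
  expect_equal(q$normalized, 0.05)
  # protein-mode x protein equals per-fly mode x n_flies
  qp <- quantifyMetabolite(0.5, cv, "protein", protein = 2.5)
  expect_equal(qp$normalized * 2.5, q$normalized * 4)
  # below-blank absorbance clamps with a warning
  expect_warning(qc <- quantifyMetabolite(0.05, cv, "per_fly", nFlies = 1),
                 "clamped")
  expect_equal(qc$amount, 0)
  expect_true(qc$clamped)
})

test_that("standard curves are gated on points and fit quality", {
  conc <- c(0, 1, 2, 4)
  expect_error(fitStandardCurve(conc[1:2], c(0, 1)), ">= 3")
  set.seed(1)
  expect_error(fitStandardCurve(conc, rnorm(4)), "R\\^2")
  fit <- fitStandardCurve(conc, 0.1 + 2 * conc + rnorm(4, 0, 0.01))
  expect_equal(fit$slope, 2, tolerance = 0.05)
})

test_that("starvation utilization matches its definition and covers truth", {
  expect_equal(starvationDelta(c(10, 10), c(4, 4))$utilization, 6)
  expect_equal(starvationDelta(c(10, 10), c(4, 4),
                               mode = "fractional")$utilization, 0.6)
  expect_equal(starvationDelta(c(5, 5), c(5, 5))$utilization, 0)
  # bootstrap CI coverage of a planted difference
  set.seed(3)
  cover <- mean(vapply(1:200, function(i) {
    fed <- rnorm(8, 10, 1)
    st <- rnorm(8, 7, 1)
    ci <- starvationDelta(fed, st, nBoot = 300, seed = i)
    ci$ciLow <= 3 && 3 <= ci$ciHigh
  }, logical(1)))
  expect_gte(cover, 0.93)
})

test_that("FLIC features merge events by the gap rule", {
  # hand-traced merge: (0,2) and (3,5) with gap 1 < 2 merge, duration 5
  f <- flicFeatures(data.frame(start = c(0, 3), end = c(2, 5)),
                    minEventGap = 2)
  expect_identical(f$nEvents, 1L)
  expect_equal(f$totalDuration, 5)
  # zero threshold keeps the raw count
  f0 <- flicFeatures(data.frame(start = c(0, 3), end = c(2, 5)),
                     minEventGap = 0)
  expect_identical(f0$nEvents, 2L)
  expect_equal(f0$totalDuration, 4)
  # empty record
  e <- flicFeatures(data.frame(start = numeric(0), end = numeric(0)))
  expect_identical(e$nEvents, 0L)
  expect_equal(e$totalDuration, 0)
  expect_error(flicFeatures(data.frame(start = 5, end = 3)), "negative")
  expect_error(flicFeatures(data.frame(start = c(0, 1), end = c(3, 4))),
               "overlap")
})

test_that("dye-choice preference follows its definition and is scale-free", {
  cv <- list(slope = 1, intercept = 0)
  expect_equal(dyeChoice(2, 2, cv, cv)$preference, 0.5)
  expect_equal(dyeChoice(1, 3, cv, cv)$preference, 0.75)
  expect_true(is.na(dyeChoice(0, 0, cv, cv)$preference))
  # doubling absorbances above the intercept doubles consumption,
  # preference unchanged
  cv2 <- list(slope = 2, intercept = 0.2)
  a <- dyeChoice(0.2 + 0.6, 0.2 + 1.0, cv2, cv2)
  b <- dyeChoice(0.2 + 1.2, 0.2 + 2.0, cv2, cv2)
  expect_equal(b$sucrose, 2 * a$sucrose)
  expect_equal(b$yeast, 2 * a$yeast)
  expect_equal(a$preference, b$preference)
})
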
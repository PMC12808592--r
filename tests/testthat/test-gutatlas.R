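test_that("a straight tube's traced length matches the endpoint distance", {
  p <- gutSimParams(lengthMalePx = 1000, curvature = 0, seed = 2)
  sim <- simulateGutImage(p, "male")
  ax <- traceAxis(sim$image)
  expect_equal(ax$lengthPx, 1000, tolerance = 1e-3)
  ep <- traceAxis(sim$image, mode = "endpoint")
  expect_equal(ep$lengthPx, 1000, tolerance = 1e-3)
})

test_that("curved gut lengths are recovered within 2% and r within 0.05", {
  p <- gutSimParams(seed = 31)
  relErr <- numeric(0)
  lens <- list(male = numeric(0), female = numeric(0))
  for (s in c("male", "female")) for (i in 1:3) {
    sim <- simulateGutImage(p, s, seed = 100 * i + (s == "female"))
    ax <- traceAxis(sim$image)
    relErr <- c(relErr, ax$lengthPx / sim$truth$lengthPx - 1)
    lens[[s]] <- c(lens[[s]], ax$lengthPx)
  }
  expect_true(all(abs(relErr) < 0.02))
  expect_equal(mean(lens$female) / mean(lens$male), 1.4, tolerance = 0.05)
})

test_that("nucleus segmentation recovers well-separated planted nuclei", {
  # sparse, non-touching configuration
  p <- gutSimParams(lengthMalePx = 1200, nucleiPerPx = 0.45,
                    minSpacing = 8, seed = 12)
  sim <- simulateGutImage(p, "male")
  cen <- segmentNuclei(nuclearChannel(sim$image))
  expect_gt(nrow(sim$truth$cells), 150)
  m <- matchCentroids(cen, sim$truth$cells, radius = 5)
  expect_gte(m["recall"], 0.95)
  expect_gte(m["precision"], 0.95)
  # determinism on the identical image
  cen2 <- segmentNuclei(nuclearChannel(sim$image))
  expect_identical(cen, cen2)
})

test_that("degenerate images yield empty or complete GFP sets, not errors", {
  blank <- matrix(0, 60, 40)
  expect_identical(nrow(segmentNuclei(blank)), 0L)
  p <- gutSimParams(lengthMalePx = 300, seed = 9)
  sim <- simulateGutImage(p, "male")
  cen <- segmentNuclei(nuclearChannel(sim$image))
  expect_true(nrow(cen) > 0)
  # GFP channel all zeros: nothing is called positive
  expect_false(any(segmentGFPCells(matrix(0, nrow(nuclearChannel(sim$image)),
                                          ncol(nuclearChannel(sim$image))),
                                   cen)))
  # every nucleus carrying a GFP blob: the subset is the full set
  pAll <- gutSimParams(lengthMalePx = 300,
                       eecFractionProfile = rep(1, 10), seed = 9)
  simAll <- simulateGutImage(pAll, "male")
  qAll <- quantifyGut(simAll$image)
  expect_true(all(cellTable(qAll)$gfp))
})

test_that("planted GFP fractions are recovered through the full pipeline", {
  p <- gutSimParams(eecFractionProfile = rep(0.3, 10), seed = 17)
  sim <- simulateGutImage(p, "female")
  q <- quantifyGut(sim$image)
  expect_lt(abs(mean(cellTable(q)$gfp) - 0.3), 0.03)
  # decile counts are conserved
  expect_identical(sum(decileCounts(q, "total")), nrow(cellTable(q)))
  expect_identical(sum(decileCounts(q, "gfp")), sum(cellTable(q)$gfp))
})

test_that("decile assignment follows the half-open binning rule", {
  d <- assignDeciles(c(0.05, 0.1, 0.95, 1))
  expect_identical(d$decile, c(0L, 1L, 9L, 9L))
  expect_error(assignDeciles(c(0.5, 1.2)), "\\[0, 1\\]")
  # conservation and multinomial balance for uniform points
  set.seed(7)
  t <- runif(1000)
  d <- assignDeciles(t)
  expect_identical(sum(d$counts), 1000L)
  expect_true(all(abs(d$counts - 100) < 5 * sqrt(100 * 0.9)))
})

test_that("female normalization and per-length density behave algebraically", {
  df <- data.frame(genotype = "g", sex = rep(c("female", "male"), each = 3),
                   value = c(14, 14, 14, 10, 10, 10))
  norm <- normalizeToFemale(df)
  expect_equal(norm$normalized[df$sex == "female"], rep(1, 3))
  expect_equal(norm$normalized[df$sex == "male"], rep(10 / 14, 3))
  # scale invariance
  df2 <- df; df2$value <- df2$value * 2
  expect_equal(normalizeToFemale(df2)$normalized, norm$normalized)
  expect_error(normalizeToFemale(df[df$sex == "male", ]), "reference")
})

test_that("count-level enrichment recovers planted folds and is symmetric", {
  set.seed(11)
  coh <- countCohort(nPerSex = 10, enrichDeciles = 3:5, fold = 2.5)
  e <- enrichmentAnalysis(coh$female, coh$male, nBoot = 500, seed = 1)
  expect_equal(lengthRatio(e), 1.4, tolerance = 1e-6)
  expect_equal(mean(enrichmentRatios(e)[4:6]), 2.5, tolerance = 0.25)
  expect_equal(mean(enrichmentRatios(e)[-(4:6)]), 1, tolerance = 0.12)
  expect_true(all(adjustedPValues(e)[4:6] < 0.05))
  # swapping the sexes inverts the planted ratios
  swapF <- lapply(coh$male, function(q)
    new("GutQuantification", lengthPx = gutLength(q), cells = q@cells,
        decileCountsTotal = q@decileCountsTotal,
        decileCountsGFP = q@decileCountsGFP, sex = "female",
        genotype = "control", mating = "mated"))
  swapM <- lapply(coh$female, function(q)
    new("GutQuantification", lengthPx = gutLength(q), cells = q@cells,
        decileCountsTotal = q@decileCountsTotal,
        decileCountsGFP = q@decileCountsGFP, sex = "male",
        genotype = "control", mating = "mated"))
  eSwap <- enrichmentAnalysis(swapF, swapM, nBoot = 10, seed = 1)
  expect_equal(enrichmentRatios(eSwap), 1 / enrichmentRatios(e),
               tolerance = 1e-8)
  expect_error(enrichmentAnalysis(coh$female[1], coh$male), "2 guts")
})

test_that("identical per-length densities give ratios near 1, none significant", {
  set.seed(23)
  coh <- countCohort(nPerSex = 10)
  e <- enrichmentAnalysis(coh$female, coh$male, nBoot = 200, seed = 1)
  expect_equal(mean(enrichmentRatios(e)), 1, tolerance = 0.1)
  expect_true(all(adjustedPValues(e) > 0.05))
  # bootstrap CI brackets the point estimate
  expect_true(all(e@ciLow <= enrichmentRatios(e) &
                    enrichmentRatios(e) <= e@ciHigh))
})

test_that("Welch ANOVA and Dunnett T3 behave on analytic cases", {
  set.seed(2)
  v <- rnorm(12)
  # two identical groups: pairwise p ~ 1
  gc0 <- groupCompare(c(v, v), rep(c("a", "b"), each = 12))
  expect_gt(gc0$pairwise$p, 0.99)
  # Welch ANOVA on 2 groups equals squared Welch t
  g <- rep(c("a", "b"), each = 6)
  x <- c(v[1:6], v[7:12] + 1)
  gc <- groupCompare(x, g)
  tt <- t.test(x[g == "a"], x[g == "b"])
  expect_equal(gc$omnibus$statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(gc$omnibus$p, tt$p.value, tolerance = 1e-10)
  expect_error(groupCompare(rep(1, 12), g), "zero within-group")
})

test_that("the omnibus p-value is uniform under the null", {
  set.seed(5)
  ps <- vapply(seq_len(1000), function(i)
    groupCompare(rnorm(15), rep(c("a", "b", "c"), each = 5))$omnibus$p,
    numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Holm-Sidak adjustment is monotone and bounded", {
  p <- c(0.01, 0.04, 0.3, 0.9)
  adj <- holmSidak(p)
  expect_equal(adj[1], 1 - (1 - 0.01)^4)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj <= 1))
  # single p-value is unchanged
  expect_equal(holmSidak(0.2), 0.2)
})
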
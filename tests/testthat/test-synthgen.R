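test_that("gut simulation parameters are validated", {
  expect_error(gutSimParams(eecFractionProfile = rep(1.2, 10)),
               "0, 1")
  expect_error(gutSimParams(eecFractionProfile = rep(0.5, 10),
                            enrichmentDeciles = c(2, 7),
                            enrichmentFold = 2.5),
               "decile 2, 7")
  expect_error(gutSimParams(lengthMalePx = -5), "positive")
  expect_s4_class(gutSimParams(enrichmentDeciles = 3:5,
                               enrichmentFold = 2.5), "GutSimParams")
})

test_that("female gut length is the ratio times the male length", {
  p <- gutSimParams(lengthMalePx = 500, lengthRatio = 1.4, seed = 3)
  m <- simulateGutImage(p, "male")
  f <- simulateGutImage(p, "female")
  expect_equal(m$truth$lengthPx, 500, tolerance = 1e-3)
  expect_equal(f$truth$lengthPx, 1.4 * 500, tolerance = 1e-3)
})

test_that("gut generation is deterministic and ground truth is consistent", {
  p <- gutSimParams(lengthMalePx = 300, seed = 8)
  a <- simulateGutImage(p, "male")
  b <- simulateGutImage(p, "male")
  expect_identical(nuclearChannel(a$image), nuclearChannel(b$image))
  expect_identical(gfpChannel(a$image), gfpChannel(b$image))
  expect_identical(a$truth$cells, b$truth$cells)
  # GFP+ set is a subset of the nucleus set; all t in [0, 1]
  expect_true(all(a$truth$cells$t >= 0 & a$truth$cells$t <= 1))
  expect_lte(sum(a$truth$cells$gfp), nrow(a$truth$cells))
})

test_that("planted enrichment multiplies the GFP fraction in expectation", {
  p <- gutSimParams(lengthMalePx = 2000, eecFractionProfile = rep(0.2, 10),
                    enrichmentDeciles = 3:5, enrichmentFold = 2.5,
                    seed = 21)
  f <- simulateGutImage(p, "female")$truth$cells
  inEnr <- f$decile %in% 3:5
  expect_lt(abs(mean(f$gfp[inEnr]) - 0.5), 0.06)
  expect_lt(abs(mean(f$gfp[!inEnr]) - 0.2), 0.04)
  # enrichment is female-specific by default
  m <- simulateGutImage(p, "male")$truth$cells
  expect_lt(abs(mean(m$gfp[m$decile %in% 3:5]) - 0.2), 0.05)
})

test_that("gut images round-trip through TIFF + JSON side-car", {
  p <- gutSimParams(lengthMalePx = 250, seed = 5)
  sim <- simulateGutImage(p, "male")
  d <- tempfile("gutimg")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  writeGutImage(sim, d, "gut1")
  back <- readGutImage(file.path(d, "gut1.tif"))
  expect_lt(max(abs(nuclearChannel(back$image) -
                      nuclearChannel(sim$image))), 1 / 65535)
  expect_equal(back$truth$lengthPx, sim$truth$lengthPx)
  expect_equal(back$truth$cells$t, sim$truth$cells$t)
  expect_identical(back$truth$cells$gfp, sim$truth$cells$gfp)
  expect_equal(unname(imageEndpoints(back$image)),
               unname(imageEndpoints(sim$image)))
})

test_that("screen tables are balanced with class-consistent ground truth", {
  sp <- screenSimParams(nGenes = 30, seed = 4)
  sim <- simulateScreenDataset(sp)
  counts <- table(sim$table$genotype, sim$table$sex, sim$table$trait)
  kd <- counts[rownames(counts) != "control", , ]
  panel <- defaultTraitPanel()
  for (tr in panel$trait)
    expect_true(all(kd[, , tr] == panel$nReplicates[panel$trait == tr]))
  # discordant genes have opposite nonzero signs; sex-specific exactly one
  tru <- sim$truth
  disc <- tru[tru$class == "discordant", ]
  expect_true(all(disc$effectFemale * disc$effectMale < 0))
  ss <- tru[tru$class == "sex_specific", ]
  expect_true(all((ss$effectFemale == 0) != (ss$effectMale == 0)))
  nul <- tru[tru$class == "null", ]
  expect_true(all(nul$effectFemale == 0 & nul$effectMale == 0))
})

test_that("an all-null screen plants no effects and validation rejects bad probs", {
  sim <- simulateScreenDataset(screenSimParams(
    nGenes = 15, effectClassProbs = c(1, 0, 0, 0), seed = 2))
  expect_true(all(sim$truth$effectFemale == 0 & sim$truth$effectMale == 0))
  expect_error(screenSimParams(effectClassProbs = c(0.5, 0.5, 0.5, 0)),
               "summing to 1")
  badPanel <- defaultTraitPanel()
  badPanel$replicateSd[1] <- 0
  expect_error(screenSimParams(traits = badPanel), "positive")
})

test_that("activity series respect planted bouts and the 5-minute rule", {
  # no bouts: ground truth 0 and scorer finds 0
  s0 <- simulateActivitySeries(NULL, seed = 1)
  expect_identical(s0$truth$sleepMinutes, 0)
  expect_identical(scoreSleep(s0$counts)$totalSleep, 0L)
  # one bout covering the whole night phase
  s1 <- simulateActivitySeries(cbind(720, 1440), seed = 2)
  expect_equal(s1$truth$sleepMinutes, 720)
  sc <- scoreSleep(s1$counts)
  expect_equal(sc$nightSleep, 720)
  expect_equal(sc$daySleep, 0)
  # 4-minute bouts sit below the scoring threshold
  s2 <- simulateActivitySeries(cbind(c(100, 300, 500), c(104, 304, 504)),
                               seed = 3)
  expect_identical(s2$truth$sleepMinutes, 0)
  expect_identical(scoreSleep(s2$counts)$totalSleep, 0L)
  # overlap rejected
  expect_error(simulateActivitySeries(cbind(c(10, 12), c(15, 20))),
               "overlap")
})

test_that("survival counts are monotone, conserved, and hazard-consistent", {
  d <- simulateSurvivalData(0.05, nVials = 3, fliesPerVial = 20,
                            checkIntervalH = 7, seed = 6)
  for (v in split(d, d$vial)) {
    expect_true(all(diff(v$cumulative_dead) >= 0))
    expect_identical(tail(v$cumulative_dead, 1), 20L)
  }
  # essentially infinite hazard: everyone dead at the first check
  dInf <- simulateSurvivalData(1e6, nVials = 2, fliesPerVial = 20,
                               checkIntervalH = 6, seed = 1)
  expect_true(all(dInf$cumulative_dead == 20L))
  expect_true(all(dInf$time_h == 6))
  expect_error(simulateSurvivalData(0.05, checkIntervalH = 12), "6, 8")
})
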
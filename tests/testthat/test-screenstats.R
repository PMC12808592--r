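test_that("max scaling maps the pooled maximum to exactly 1", {
  expect_equal(scaleToMax(c(2, 4, 8)), c(0.25, 0.5, 1))
  set.seed(1)
  x <- rexp(50)
  s <- scaleToMax(x)
  expect_identical(max(s), 1)
  expect_equal(cor(rank(x), rank(s)), 1)
  expect_error(scaleToMax(c(0, 0)), "all-zero")
})

test_that("z-scores match the hand-computed SD-across-means example", {
  # knockdown means 1..5, control 3: S = sd(1:5) = 1.5811,
  # z(mean 5) = 2 / 1.5811 = 1.2649 -> not a hit at 1.5
  tab <- meansTable(setNames(as.list(1:5), paste0("g", 1:5)), control = 3)
  h <- callHits(tab, minKnockdowns = 5)
  hc <- hitCalls(h)
  expect_equal(h@traitSD$sd, sd(1:5))
  expect_equal(hc$z[hc$gene == "g5"], 2 / sd(1:5), tolerance = 1e-9)
  expect_false(hc$hit[hc$gene == "g5"])
  expect_equal(hc$z[hc$gene == "g3"], 0)
  # hit calling is invariant under affine rescaling of the trait
  tab2 <- tab
  tab2$value <- 100 + 7 * tab2$value
  hc2 <- hitCalls(callHits(tab2, minKnockdowns = 5))
  expect_equal(hc2$z, hc$z, tolerance = 1e-9)
  expect_identical(hc2$hit, hc$hit)
})

test_that("hit calling validates its inputs", {
  tab <- meansTable(setNames(as.list(1:5), paste0("g", 1:5)), control = 3)
  expect_error(callHits(tab), "fewer than 10")
  degenerate <- meansTable(setNames(as.list(rep(2, 5)), paste0("g", 1:5)),
                           control = 2)
  expect_error(callHits(degenerate, minKnockdowns = 5), "SD is zero")
  noCtl <- tab[tab$genotype != "control", ]
  expect_error(callHits(noCtl, minKnockdowns = 5), "control")
})

test_that("null screens hit at the Gaussian tail rate", {
  set.seed(41)
  fr <- vapply(1:40, function(i) {
    sp <- screenSimParams(nGenes = 165, traits = defaultTraitPanel()[4, ],
                          effectClassProbs = c(1, 0, 0, 0),
                          controlReplicates = 1000, seed = 7000 + i)
    mean(hitCalls(callHits(simulateScreenDataset(sp)$table))$hit)
  }, numeric(1))
  oracle <- 2 * (1 - pnorm(1.5))
  n <- 40 * 165 * 2
  expect_lt(abs(mean(fr) - oracle),
            2.576 * sqrt(oracle * (1 - oracle) / n) + 0.002)
})

test_that("Venn fractions reproduce the printed screen identities", {
  # fed glycogen: 89 male-only, 8 female-only, 38 shared
  gly <- vennTriple(89, 8, 38)
  expect_equal(gly$femaleShared, 38 / 46)
  expect_identical(gly$femaleShared_pct, 83)
  expect_identical(gly$maleSpecific_pct, 70)
  expect_equal(gly$maleSpecific + gly$maleShared, 1)
  # starvation survival: 16/16/6
  stv <- vennTriple(16, 16, 6)
  expect_identical(stv$femaleShared_pct, 27)
  # zero hits in a sex reports NA, not 0
  expect_true(is.na(vennTriple(0, 0, 5)$femaleSpecific) == FALSE)
  expect_true(is.na(vennTriple(5, 0, 0)$femaleShared))
})

test_that("the atlas crosses per-sex hit sets gene by gene", {
  genes <- sprintf("g%02d", 1:30)
  means <- setNames(as.list(rep(0, 30)), genes)
  # plant hits by shifting selected means far from control
  mkTab <- function(hitF, hitM) {
    mf <- means; mf[hitF] <- 50
    mm <- means; mm[hitM] <- 50
    rbind(meansTable(mf, control = 0, sex = "female"),
          meansTable(mm, control = 0, sex = "male"))
  }
  tab <- mkTab(genes[1:6], genes[4:12])
  atlas <- sexSpecificityAtlas(callHits(tab))
  expect_identical(atlas$venn$shared, 3L)
  expect_identical(atlas$venn$femaleOnly, 3L)
  expect_identical(atlas$venn$maleOnly, 6L)
  expect_equal(atlas$atlas["t1", "female"], 0.5)
})

test_that("concordance classifies identical, flipped, and discordant effects", {
  genes <- paste0("g", 1:12)
  set.seed(6)
  zs <- rnorm(12, 0, 2)
  means <- setNames(as.list(zs), genes)
  tab <- rbind(meansTable(means, control = 0, sex = "female"),
               meansTable(means, control = 0, sex = "male"))
  cs <- suppressWarnings(concordanceScatter(callHits(tab), "t1"))
  expect_equal(cs$fit$slope, 1, tolerance = 1e-9)
  expect_equal(cs$fit$r2, 1, tolerance = 1e-9)
  expect_true(all(cs$genes$class != "discordant"))
  # flipping all male effects flips the slope exactly
  mflip <- setNames(as.list(-zs), genes)
  tabf <- rbind(meansTable(means, control = 0, sex = "female"),
                meansTable(mflip, control = 0, sex = "male"))
  csf <- suppressWarnings(concordanceScatter(callHits(tabf), "t1"))
  expect_equal(csf$fit$slope, -cs$fit$slope, tolerance = 1e-9)
})

test_that("planted discordant genes are recovered as discordant", {
  # Monte-Carlo over screens; per-gene detection needs both sexes past the
  # cutoff, so the ceiling at 3-SD effects is P(|z|>1.5)^2 ~ 0.87, and
  # planted effects must stay sparse to keep the screen SD noise-dominated
  set.seed(77)
  hits <- 0L
  tot <- 0L
  for (i in 1:30) {
    sp <- screenSimParams(nGenes = 165, traits = defaultTraitPanel()[4, ],
                          effectClassProbs = c(0.97, 0, 0, 0.03),
                          controlReplicates = 1000, seed = 8000 + i)
    sim <- simulateScreenDataset(sp)
    cs <- concordanceScatter(callHits(sim$table), "tag_fed")
    disc <- sim$truth$gene[sim$truth$class == "discordant"]
    tot <- tot + length(disc)
    hits <- hits + sum(cs$genes$class[match(disc, cs$genes$gene)] ==
                         "discordant")
  }
  expect_gte(hits / tot, 0.75)
})

test_that("trait correlations report exact fits and uniform null p-values", {
  genes <- paste0("g", 1:15)
  set.seed(4)
  xv <- rnorm(15)
  tabx <- do.call(rbind, lapply(c("female", "male"), function(sx) rbind(
    meansTable(setNames(as.list(xv), genes), control = 0, trait = "x",
               sex = sx),
    meansTable(setNames(as.list(2 * xv), genes), control = 0, trait = "y",
               sex = sx))))
  tc <- suppressWarnings(traitCorrelation(tabx, "x", "y"))
  expect_equal(tc$slope, c(2, 2), tolerance = 1e-9)
  expect_equal(tc$r2, c(1, 1), tolerance = 1e-9)
  # independent traits: slope p uniform across simulations
  ps <- vapply(1:400, function(i) {
    set.seed(9000 + i)
    tabr <- rbind(
      meansTable(setNames(as.list(rnorm(15)), genes), control = 0,
                 trait = "x"),
      meansTable(setNames(as.list(rnorm(15)), genes), control = 0,
                 trait = "y"))
    traitCorrelation(tabr, "x", "y")$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Spearman profiles respect rank identities and monotone maps", {
  set.seed(10)
  m <- matrix(rnorm(60), 3, 20,
              dimnames = list(c("a", "b", "c"), NULL))
  m[2, ] <- -m[1, ]
  ps <- pairwiseSpearman(m)
  expect_equal(ps$r["a", "a"], 1)
  expect_equal(ps$r["a", "b"], -1)
  expect_equal(ps$p["a", "b"], 0)
  # invariance under strictly increasing transforms
  m2 <- m
  m2[1, ] <- exp(3 * m2[1, ])
  m2[3, ] <- m2[3, ]^3 + 5 * m2[3, ]
  ps2 <- pairwiseSpearman(m2)
  expect_equal(ps2$r, ps$r, tolerance = 1e-12)
  # too few shared traits reported missing
  m3 <- matrix(rnorm(20), 2, 10)
  m3[1, 1:7] <- NA
  expect_true(is.na(pairwiseSpearman(m3, minShared = 5)$r[1, 2]))
})
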
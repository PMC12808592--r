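#' Default 18-trait phenotype panel for screen simulation
#'
#' One row per trait with sex-specific control means, replicate-level noise
#' SD and replicate counts mirroring a multi-assay knockdown screen:
#' survival under three stressors (3 vials), metabolite levels and
#' starvation utilization (4 replicates), FLIC feeding (12 flies) and
#' day/night sleep in fed and starved states (32 flies). Control means are
#' sexually dimorphic in the directions seen in flies (females: more fat and
#' glycogen, longer stress survival, more feeding, less sleep); glucose is
#' close to monomorphic.
#'
#' @return data.frame with columns `trait`, `controlFemale`, `controlMale`,
#'   `replicateSd`, `nReplicates`.
#' @export
defaultTraitPanel <- function() {
  data.frame(
    trait = c("starvation_survival", "ionic_survival", "oxidative_survival",
              "tag_fed", "tag_starved", "tag_utilization",
              "glycogen_fed", "glycogen_starved", "glycogen_utilization",
              "glucose_fed", "glucose_starved", "glucose_utilization",
              "feeding_events", "feeding_duration",
              "sleep_day_fed", "sleep_night_fed",
              "sleep_day_starved", "sleep_night_starved"),
    controlFemale = c(60, 50, 40, 8, 4, 4, 6, 3, 3, 2, 1.5, 0.5,
                      45, 900, 300, 480, 200, 350),
    controlMale = c(40, 38, 30, 5, 2.5, 2.5, 4.5, 2, 2.5, 1.9, 1.4, 0.5,
                    25, 500, 420, 600, 320, 520),
    replicateSd = c(6, 6, 5, 0.8, 0.5, 0.6, 0.6, 0.4, 0.5, 0.25, 0.2, 0.15,
                    8, 150, 60, 50, 60, 60),
    nReplicates = c(3L, 3L, 3L, 4L, 4L, 4L, 4L, 4L, 4L, 4L, 4L, 4L,
                    12L, 12L, 32L, 32L, 32L, 32L))
}

#' Construct parameters for the synthetic screen generator
#'
#' Each gene is assigned exactly one ground-truth effect class per trait:
#' `null` (no effect in either sex), `shared` (same signed effect in both
#' sexes), `sex_specific` (effect in one randomly chosen sex), or
#' `discordant` (opposite signs in the two sexes, both nonzero). Effect
#' magnitudes are `effectSizeSd` standard errors of a knockdown mean
#' (`replicateSd / sqrt(nReplicates)`), with random sign. The default class
#' probabilities keep planted effects sparse, so that the across-knockdown
#' SD used for z-score hit calling remains dominated by measurement noise.
#'
#' @param nGenes number of knockdown genotypes.
#' @param traits trait panel data.frame as from [defaultTraitPanel()].
#' @param effectClassProbs probabilities over
#'   (null, shared, sex_specific, discordant); must sum to 1.
#' @param effectSizeSd effect magnitude in knockdown-mean SD units.
#' @param controlReplicates replicate count for the control genotype
#'   (default: same as each trait's knockdown replicate count).
#' @param plantAbolishing if TRUE, gene 1 is planted as a
#'   "dimorphism-abolishing" knockdown: its female means equal the male
#'   control means (the female profile becomes male-like).
#' @param plantEnhancing if TRUE, gene 2 is planted as a
#'   "dimorphism-enhancing" knockdown: each sex is pushed 50% further from
#'   the other sex's control.
#' @param seed integer RNG seed.
#' @return validated parameter list of class `ScreenSimParams`.
#' @export
screenSimParams <- function(nGenes = 165L, traits = defaultTraitPanel(),
                            effectClassProbs = c(null = 0.94, shared = 0.02,
                                                 sex_specific = 0.03,
                                                 discordant = 0.01),
                            effectSizeSd = 3, controlReplicates = NULL,
                            plantAbolishing = FALSE, plantEnhancing = FALSE,
                            seed = 1L) {
  stopifnot(nGenes >= 1, nrow(traits) >= 1,
            all(c("trait", "controlFemale", "controlMale", "replicateSd",
                  "nReplicates") %in% names(traits)))
  if (any(traits$replicateSd <= 0))
    stop("replicate SD must be positive for every trait")
  if (any(traits$nReplicates < 2L))
    stop("replicate counts must be >= 2")
  if (length(effectClassProbs) != 4L || any(effectClassProbs < 0) ||
      abs(sum(effectClassProbs) - 1) > 1e-8)
    stop("effectClassProbs must be 4 nonnegative probabilities summing to 1")
  if (effectSizeSd <= 0) stop("effectSizeSd must be positive")
  structure(list(nGenes = as.integer(nGenes), traits = traits,
                 effectClassProbs = effectClassProbs,
                 effectSizeSd = effectSizeSd,
                 controlReplicates = controlReplicates,
                 plantAbolishing = plantAbolishing,
                 plantEnhancing = plantEnhancing,
                 seed = as.integer(seed)),
            class = "ScreenSimParams")
}

#' Simulate a replicate-level phenotype screen with ground truth
#'
#' Control replicates are drawn around the sex-specific control mean;
#' knockdown replicates are shifted by the class-dependent signed effect.
#' The output table is tidy (`genotype`, `sex`, `trait`, `replicate`,
#' `value`) with the control genotype labelled `"control"`, balanced over
#' gene x sex x trait.
#'
#' @param params result of [screenSimParams()].
#' @return list with `table` (tidy data.frame) and `truth` (data.frame with
#'   one row per gene x trait: `class`, `effectFemale`, `effectMale` in
#'   knockdown-mean SD units, plus the special planted role if any).
#' @export
#' @examples
#' sim <- simulateScreenDataset(screenSimParams(nGenes = 20, seed = 3))
#' head(sim$table)
simulateScreenDataset <- function(params) {
  stopifnot(inherits(params, "ScreenSimParams"))
  withSeed(params$seed, {
    tr <- params$traits
    genes <- sprintf("gene_%03d", seq_len(params$nGenes))
    classes <- c("null", "shared", "sex_specific", "discordant")

    truth <- do.call(rbind, lapply(seq_len(params$nGenes), function(g) {
      cl <- sample(classes, nrow(tr), replace = TRUE,
                   prob = params$effectClassProbs)
      sgn <- sample(c(-1, 1), nrow(tr), replace = TRUE)
      fem <- mal <- numeric(nrow(tr))
      e <- params$effectSizeSd
      shared <- cl == "shared"
      fem[shared] <- sgn[shared] * e; mal[shared] <- sgn[shared] * e
      ss <- cl == "sex_specific"
      whichF <- runif(nrow(tr)) < 0.5
      fem[ss & whichF] <- sgn[ss & whichF] * e
      mal[ss & !whichF] <- sgn[ss & !whichF] * e
      disc <- cl == "discordant"
      fem[disc] <- sgn[disc] * e; mal[disc] <- -sgn[disc] * e
      data.frame(gene = genes[g], trait = tr$trait, class = cl,
                 effectFemale = fem, effectMale = mal, role = "knockdown")
    }))

    if (params$plantAbolishing && params$nGenes >= 1L)
      truth$role[truth$gene == genes[1]] <- "abolishing"
    if (params$plantEnhancing && params$nGenes >= 2L)
      truth$role[truth$gene == genes[2]] <- "enhancing"

    semu <- tr$replicateSd / sqrt(tr$nReplicates)
    rows <- vector("list", 2L * (params$nGenes + 1L) * nrow(tr))
    k <- 0L
    for (ti in seq_len(nrow(tr))) {
      nrep <- tr$nReplicates[ti]
      ncrep <- if (is.null(params$controlReplicates)) nrep
      else as.integer(params$controlReplicates)
      for (sx in c("female", "male")) {
        cm <- if (sx == "female") tr$controlFemale[ti] else tr$controlMale[ti]
        k <- k + 1L
        rows[[k]] <- data.frame(
          genotype = "control", sex = sx, trait = tr$trait[ti],
          replicate = seq_len(ncrep),
          value = rnorm(ncrep, cm, tr$replicateSd[ti]))
        tt <- truth[truth$trait == tr$trait[ti], ]
        eff <- if (sx == "female") tt$effectFemale else tt$effectMale
        mu <- cm + eff * semu[ti]
        mu[tt$role == "abolishing"] <- tr$controlMale[ti]
        if (any(tt$role == "enhancing")) {
          gap <- tr$controlFemale[ti] - tr$controlMale[ti]
          mu[tt$role == "enhancing"] <- cm +
            0.5 * gap * if (sx == "female") 1 else -1
        }
        vals <- rnorm(params$nGenes * nrep,
                      rep(mu, each = nrep), tr$replicateSd[ti])
        k <- k + 1L
        rows[[k]] <- data.frame(
          genotype = rep(tt$gene, each = nrep), sex = sx,
          trait = tr$trait[ti], replicate = rep(seq_len(nrep), params$nGenes),
          value = vals)
      }
    }
    tab <- do.call(rbind, rows[seq_len(k)])
    rownames(tab) <- NULL
    list(table = tab, truth = truth)
  })
}
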
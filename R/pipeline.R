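#' Default end-to-end pipeline configuration
#'
#' One flat list of defaults; [runPipeline()] accepts a modified copy or a
#' YAML file with any subset of these fields. Tunables default to the
#' conventions used throughout: z cutoff 1.5, 10 deciles, 5-minute sleep
#' threshold, 7 h survival checks, 12:12 photoperiod.
#'
#' @param outDir output directory.
#' @param seed integer seed for all stages.
#' @return configuration list.
#' @export
defaultRunConfig <- function(outDir = tempfile("dimorph-run"), seed = 1L) {
  list(
    seed = as.integer(seed),
    outDir = outDir,
    gut = list(nPerSex = 4L, lengthMalePx = 400, enrichmentDeciles = 3:5,
               enrichmentFold = 2.5, bootstrap = 500L),
    screen = list(nGenes = 40L, cutoff = 1.5, plantAbolishing = TRUE),
    sleep = list(threshold = 5L, lightsOnMinute = 0L),
    survival = list(hazard = 0.04, nVials = 3L, fliesPerVial = 20L,
                    checkIntervalH = 7)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  merge2 <- function(base, over) {
    for (k in names(over))
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge2(base[[k]], over[[k]]) else over[[k]]
    base
  }
  merge2(cfg, user)
}

#' Run the full synthetic-screen pipeline
#'
#' Executes simulate -> quantify -> assays -> screen -> multivar -> report,
#' writing tidy CSV outputs and a JSON run manifest (config snapshot,
#' package version, per-stage record counts and wall-clock, output
#' checksums) sufficient to reproduce the run. Deterministic given the
#' seed.
#'
#' @param config configuration list (see [defaultRunConfig()]) or a path
#'   to a YAML file.
#' @param quiet suppress stage messages.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = defaultRunConfig(), quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      unlink(file.path(out, "INCOMPLETE"), force = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0,
                                            2))
    say("stage %s done (%.1fs)", name, stages[[name]]$seconds)
    res
  }

  # simulate
  sims <- stage("simulate", {
    gp <- gutSimParams(lengthMalePx = config$gut$lengthMalePx,
                       enrichmentDeciles = config$gut$enrichmentDeciles,
                       enrichmentFold = config$gut$enrichmentFold,
                       seed = config$seed)
    cohort <- simulateGutCohort(gp, config$gut$nPerSex)
    sp <- screenSimParams(nGenes = config$screen$nGenes,
                          plantAbolishing = isTRUE(
                            config$screen$plantAbolishing),
                          seed = config$seed)
    screen <- simulateScreenDataset(sp)
    writePhenotypeTable(screen$table, file.path(out, "phenotypes.csv"))
    act <- simulateActivitySeries(cbind(c(60, 800), c(200, 1100)),
                                  seed = config$seed)
    writeDams(act$counts, file.path(out, "activity.txt"))
    surv <- simulateSurvivalData(config$survival$hazard,
                                 config$survival$nVials,
                                 config$survival$fliesPerVial,
                                 config$survival$checkIntervalH,
                                 seed = config$seed)
    write.csv(surv, file.path(out, "survival.csv"), row.names = FALSE)
    list(cohort = cohort, screen = screen, act = act, surv = surv)
  })
  stages$simulate$records <- nrow(sims$screen$table)

  # quantify gut images
  enr <- stage("quantify", {
    qf <- lapply(sims$cohort$female, function(s) quantifyGut(s$image))
    qm <- lapply(sims$cohort$male, function(s) quantifyGut(s$image))
    e <- enrichmentAnalysis(qf, qm, nBoot = config$gut$bootstrap,
                            seed = config$seed)
    write.csv(data.frame(decile = 1:10, expected = e@expected,
                         observed = e@observed, ratio = e@ratio,
                         ciLow = e@ciLow, ciHigh = e@ciHigh,
                         pAdjusted = e@pAdjusted),
              file.path(out, "enrichment.csv"), row.names = FALSE)
    e
  })
  stages$quantify$records <- 2L * config$gut$nPerSex

  # assays
  assay <- stage("assays", {
    sl <- scoreSleep(sims$act$counts, config$sleep$lightsOnMinute,
                     config$sleep$threshold)
    sv <- summarizeSurvival(sims$surv,
                            fliesPerVial = config$survival$fliesPerVial)
    write.csv(sl, file.path(out, "sleep.csv"), row.names = FALSE)
    write.csv(sv$vials, file.path(out, "survival-medians.csv"),
              row.names = FALSE)
    list(sleep = sl, survival = sv)
  })
  stages$assays$records <- nrow(assay$sleep) + nrow(assay$survival$vials)

  # screen statistics
  hits <- stage("screen", {
    h <- callHits(sims$screen$table, cutoff = config$screen$cutoff)
    atlas <- sexSpecificityAtlas(h)
    write.csv(hitCalls(h), file.path(out, "hits.csv"), row.names = FALSE)
    write.csv(atlas$venn, file.path(out, "venn.csv"), row.names = FALSE)
    write.csv(atlas$atlas, file.path(out, "atlas.csv"))
    h
  })
  stages$screen$records <- nrow(hitCalls(hits))

  # multivariate layer
  stage("multivar", {
    pmat <- buildProfileMatrix(sims$screen$table, mode = "absolute")
    emb <- phenotypePCA(pmat)
    dist <- pcaDistances(emb, "control|male",
                         rows = rownames(pcaScores(emb))[
                           profileRowInfo(emb)$sex == "female"])
    pairs <- sexPairDistances(emb)
    hcl <- hclusterProfiles(pmat)
    write.csv(pcaScores(emb), file.path(out, "pca-scores.csv"))
    write.csv(dist, file.path(out, "distance-to-male-control.csv"),
              row.names = FALSE)
    write.csv(pairs, file.path(out, "sex-pair-distances.csv"),
              row.names = FALSE)
    writeLines(hcl$order, file.path(out, "leaf-order.txt"))
    with(hcl$hclust, write.csv(
      data.frame(merge1 = merge[, 1], merge2 = merge[, 2], height = height),
      file.path(out, "linkage.csv"), row.names = FALSE))
    NULL
  })

  files <- list.files(out, full.names = TRUE)
  manifest <- list(config = config,
                   package = as.character(packageVersion("DimorphScreen")),
                   stages = stages,
                   checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
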
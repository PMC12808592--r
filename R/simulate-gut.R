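#' Construct parameters for the synthetic gut-image generator
#'
#' Defaults describe the study conditions the generator emulates: a male
#' midgut of 1000 px arc length with the female gut 1.4x longer, equal
#' per-length nucleus density in both sexes, a uniform 30% GFP+ (EEC)
#' fraction, and (optionally) a multiplicative female mid-gut enrichment of
#' the GFP+ fraction.
#'
#' @param lengthMalePx male gut arc length in px.
#' @param lengthRatio female:male arc-length ratio.
#' @param tubeWidthPx tube diameter in px.
#' @param nucleiPerPx linear nucleus density (nuclei per px of axis).
#' @param eecFractionProfile per-decile GFP+ probability, length 10.
#' @param enrichmentDeciles 0-based deciles receiving the enrichment.
#' @param enrichmentFold multiplicative enrichment of the GFP+ probability.
#' @param enrichmentSex sex carrying the enrichment (default female).
#' @param curvature relative bending amplitude of the centerline.
#' @param noiseSd additive Gaussian pixel noise sd.
#' @param blobSigma Gaussian sd of a rendered nucleus, px.
#' @param minSpacing hard-core minimum nucleus spacing, px.
#' @param pixelSize physical pixel size, micrometres per px.
#' @param seed integer RNG seed.
#' @return a [GutSimParams-class] object.
#' @export
#' @examples
#' p <- gutSimParams(enrichmentDeciles = 3:5, enrichmentFold = 2.5)
gutSimParams <- function(lengthMalePx = 1000, lengthRatio = 1.4,
                         tubeWidthPx = 36, nucleiPerPx = 0.7,
                         eecFractionProfile = rep(0.3, 10),
                         enrichmentDeciles = integer(0), enrichmentFold = 1,
                         enrichmentSex = "female", curvature = 0.05,
                         noiseSd = 0.02, blobSigma = 1.5, minSpacing = 5,
                         pixelSize = 1, seed = 1L) {
  new("GutSimParams", lengthMalePx = lengthMalePx, lengthRatio = lengthRatio,
      tubeWidthPx = tubeWidthPx, nucleiPerPx = nucleiPerPx,
      eecFractionProfile = eecFractionProfile,
      enrichmentDeciles = as.integer(enrichmentDeciles),
      enrichmentFold = enrichmentFold, enrichmentSex = enrichmentSex,
      curvature = curvature, noiseSd = noiseSd, blobSigma = blobSigma,
      minSpacing = minSpacing, pixelSize = pixelSize, seed = as.integer(seed))
}

# Smooth cubic centerline of a requested arc length; returns points spaced
# ~1 px in arc length plus the cumulative arc length (polyline integration,
# 0.25 px step, so the total is accurate to well under 0.1 px).
makeCenterline <- function(targetLength, curvature) {
  if (curvature <= 0) {
    xs <- seq(0, targetLength, by = 1)
    if (tail(xs, 1) < targetLength) xs <- c(xs, targetLength)
    return(list(points = cbind(x = xs, y = rep(0, length(xs))),
                s = xs, length = targetLength))
  }
  amp <- curvature * targetLength
  nCtrl <- 6L
  yc <- runif(nCtrl, -1, 1) * amp
  X <- targetLength
  for (it in 1:30) {
    xc <- seq(0, X, length.out = nCtrl)
    f <- splinefun(xc, yc, method = "natural")
    xs <- seq(0, X, by = 0.25)
    ys <- f(xs)
    s <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
    if (abs(s - targetLength) < 0.02) break
    X <- X * targetLength / s
  }
  cs <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  si <- seq(0, cs[length(cs)], by = 1)
  px <- approx(cs, xs, xout = si)$y
  py <- approx(cs, ys, xout = si)$y
  list(points = cbind(x = px, y = py), s = si, length = cs[length(cs)])
}

# Gaussian blobs added in place around sub-pixel centres.
addBlobs <- function(mat, xs, ys, sigma, amps) {
  if (!length(xs)) return(mat)
  r <- ceiling(4 * sigma)
  nx <- nrow(mat); ny <- ncol(mat)
  for (i in seq_along(xs)) {
    ix <- max(1, round(xs[i]) - r):min(nx, round(xs[i]) + r)
    iy <- max(1, round(ys[i]) - r):min(ny, round(ys[i]) + r)
    gx <- exp(-((ix - xs[i])^2) / (2 * sigma^2))
    gy <- exp(-((iy - ys[i])^2) / (2 * sigma^2))
    mat[ix, iy] <- mat[ix, iy] + amps[i] * outer(gx, gy)
  }
  mat
}

# Hard-core thinning: keep points at least minSpacing apart (greedy, in
# sampling order).
hardCore <- function(x, y, minSpacing) {
  n <- length(x)
  if (n <= 1L || minSpacing <= 0) return(rep(TRUE, n))
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  m2 <- minSpacing^2
  for (i in seq_len(n)) {
    if (!length(kx) || min((kx - x[i])^2 + (ky - y[i])^2) >= m2) {
      keep[i] <- TRUE
      kx <- c(kx, x[i]); ky <- c(ky, y[i])
    }
  }
  keep
}

#' Simulate a two-channel gut image with ground truth
#'
#' Renders a curved tubular midgut as a two-channel maximum-projection
#' proxy: nuclei are placed by a Poisson process along the arc length
#' (hard-core thinned), jittered transversely within the tube, and drawn as
#' Gaussian blobs in the nuclear channel; the GFP channel lights the subset
#' of nuclei drawn GFP-positive according to the per-decile profile (with
#' the enrichment fold applied in the enriched sex). Additive Gaussian noise
#' is clipped to [0, 1]. The female gut is `lengthRatio` times the male arc
#' length. The generator is a pure function of `(params, sex)`.
#'
#' @param params a [GutSimParams-class] object.
#' @param sex `"male"` or `"female"`.
#' @param seed optional seed overriding `params@seed` (used by
#'   [simulateGutCohort()] to vary replicate guts).
#' @return list with elements `image` (a [GutImage-class]) and `truth`
#'   (list: `cells` data.frame with true x, y, arc fraction `t`, 0-based
#'   `decile` and `gfp` label; `lengthPx`; `centerline`; `profile`).
#' @export
#' @examples
#' sim <- simulateGutImage(gutSimParams(lengthMalePx = 300, seed = 7), "male")
#' sim$truth$lengthPx
simulateGutImage <- function(params, sex = c("male", "female"), seed = NULL) {
  stopifnot(is(params, "GutSimParams"))
  validObject(params)
  sex <- match.arg(sex)
  if (is.null(seed)) seed <- params@seed + (sex == "female")
  withSeed(seed, {
    L <- params@lengthMalePx * if (sex == "female") params@lengthRatio else 1
    cl <- makeCenterline(L, params@curvature)
    pts <- cl$points
    trueL <- cl$length

    # place nuclei along the axis
    n0 <- rpois(1, trueL * params@nucleiPerPx)
    t0 <- runif(n0)
    idx <- pmin(nrow(pts), round(t0 * trueL) + 1L)
    tang <- pts[pmin(nrow(pts), idx + 1L), , drop = FALSE] -
      pts[pmax(1L, idx - 1L), , drop = FALSE]
    tn <- sqrt(rowSums(tang^2)); tn[tn == 0] <- 1
    nxv <- -tang[, 2] / tn; nyv <- tang[, 1] / tn
    u <- runif(n0, -0.8, 0.8) * (params@tubeWidthPx / 2 - 2)
    cx <- pts[idx, 1] + u * nxv
    cy <- pts[idx, 2] + u * nyv
    keep <- hardCore(cx, cy, params@minSpacing)
    cx <- cx[keep]; cy <- cy[keep]; t0 <- t0[keep]
    n <- length(cx)

    # GFP labels per decile profile (+ enrichment in the enriched sex)
    dec <- pmin(floor(10 * t0), 9)
    p <- params@eecFractionProfile[dec + 1L]
    if (sex == params@enrichmentSex && length(params@enrichmentDeciles))
      p <- ifelse(dec %in% params@enrichmentDeciles,
                  pmin(1, p * params@enrichmentFold), p)
    gfp <- runif(n) < p

    # canvas
    margin <- params@tubeWidthPx / 2 + 4 * params@blobSigma + 6
    ox <- margin - min(pts[, 1]); oy <- margin - min(pts[, 2])
    nx <- ceiling(max(pts[, 1]) + ox + margin)
    ny <- ceiling(max(pts[, 2]) + oy + margin)
    cx <- cx + ox; cy <- cy + oy
    clx <- pts[, 1] + ox; cly <- pts[, 2] + oy

    # tube mask by stamping the centerline and dilating with a disc
    tube <- matrix(FALSE, nx, ny)
    tube[cbind(pmin(nx, pmax(1, round(clx))),
               pmin(ny, pmax(1, round(cly))))] <- TRUE
    bw <- round(params@tubeWidthPx)
    if (bw %% 2 == 0) bw <- bw + 1
    tube <- EBImage::dilate(EBImage::Image(tube * 1),
                            EBImage::makeBrush(bw, "disc")) > 0.5
    tube <- matrix(as.logical(tube), nx, ny)

    nuc <- matrix(0, nx, ny)
    nuc[tube] <- 0.15
    nuc <- addBlobs(nuc, cx, cy, params@blobSigma,
                    0.55 + runif(n, -0.1, 0.1))
    gf <- matrix(0, nx, ny)
    gf[tube] <- 0.04
    if (any(gfp))
      gf <- addBlobs(gf, cx[gfp], cy[gfp], params@blobSigma,
                     0.6 + runif(sum(gfp), -0.1, 0.1))
    if (params@noiseSd > 0) {
      nuc <- nuc + rnorm(length(nuc), 0, params@noiseSd)
      gf <- gf + rnorm(length(gf), 0, params@noiseSd)
    }
    nuc <- clip01(nuc); gf <- clip01(gf)

    ep <- rbind(anterior = c(clx[1], cly[1]),
                posterior = c(clx[length(clx)], cly[length(cly)]))
    colnames(ep) <- c("x", "y")
    img <- new("GutImage", nuclear = nuc, gfp = gf,
               pixelSize = params@pixelSize, endpoints = ep, sex = sex,
               mating = "mated", driver = "synthetic")
    truth <- list(
      cells = data.frame(x = cx, y = cy, t = t0, decile = dec, gfp = gfp),
      lengthPx = trueL,
      centerline = cbind(x = clx, y = cly),
      profile = params@eecFractionProfile,
      enrichmentDeciles = params@enrichmentDeciles,
      enrichmentFold = params@enrichmentFold,
      sex = sex, seed = seed)
    list(image = img, truth = truth)
  })
}

#' Simulate a cohort of male and female gut images
#'
#' @param params a [GutSimParams-class] object.
#' @param nPerSex guts per sex.
#' @return list with elements `female` and `male`, each a list of
#'   `simulateGutImage()` results.
#' @export
simulateGutCohort <- function(params, nPerSex = 10L) {
  base <- params@seed
  lapply(setNames(c("female", "male"), c("female", "male")), function(s) {
    lapply(seq_len(nPerSex), function(i) {
      sd <- (base + 7919L * i + 104729L * (s == "female")) %%
        .Machine$integer.max
      simulateGutImage(params, s, seed = sd)
    })
  })
}

#' Write a simulated gut image as 16-bit TIFF plus JSON side-car
#'
#' The multi-page TIFF holds the nuclear channel first, then GFP; the JSON
#' side-car records endpoints, pixel size, labels and the full ground truth
#' so it round-trips losslessly.
#'
#' @param sim result of [simulateGutImage()].
#' @param dir output directory (created if needed).
#' @param name file stem; writes `<name>.tif` and `<name>.json`.
#' @return invisibly, the two file paths.
#' @export
writeGutImage <- function(sim, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- sim$image
  tp <- file.path(dir, paste0(name, ".tif"))
  jp <- file.path(dir, paste0(name, ".json"))
  tiff::writeTIFF(list(t(nuclearChannel(img)), t(gfpChannel(img))),
                  tp, bits.per.sample = 16L)
  side <- list(
    pixelSize = img@pixelSize,
    endpoints = unname(imageEndpoints(img)),
    sex = img@sex, mating = img@mating, driver = img@driver,
    truth = list(cells = sim$truth$cells, lengthPx = sim$truth$lengthPx,
                 seed = sim$truth$seed))
  jsonlite::write_json(side, jp, digits = NA, auto_unbox = TRUE)
  invisible(c(tiff = tp, json = jp))
}

#' Read a gut image written by [writeGutImage()]
#'
#' @param tiffPath path to the multi-page TIFF.
#' @param jsonPath path to the JSON side-car (default: same stem).
#' @return list with `image` (a [GutImage-class]) and `truth` (list or NULL).
#' @export
readGutImage <- function(tiffPath, jsonPath = sub("\\.tiff?$", ".json",
                                                  tiffPath)) {
  pages <- tiff::readTIFF(tiffPath, all = TRUE)
  if (length(pages) < 2L)
    stop("expected a two-page TIFF (nuclear, GFP)")
  side <- if (file.exists(jsonPath)) jsonlite::read_json(jsonPath,
                                                         simplifyVector = TRUE)
  else NULL
  ep <- if (!is.null(side)) matrix(unlist(side$endpoints), 2, 2,
                                   dimnames = list(c("anterior", "posterior"),
                                                   c("x", "y")))
  else rbind(anterior = c(1, 1), posterior = dim(t(pages[[1]])))
  img <- new("GutImage", nuclear = t(pages[[1]]), gfp = t(pages[[2]]),
             pixelSize = if (!is.null(side)) side$pixelSize else 1,
             endpoints = ep,
             sex = if (!is.null(side)) side$sex else "female",
             mating = if (!is.null(side)) side$mating else "mated",
             driver = if (!is.null(side)) side$driver else "unknown")
  list(image = img, truth = side$truth)
}
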
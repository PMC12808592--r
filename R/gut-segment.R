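#' Segment nuclei from the nuclear channel
#'
#' Gaussian blur, Otsu threshold, then an intensity-based watershed on the
#' masked blurred image to split touching nuclei (each nucleus is an
#' intensity peak; a distance-transform watershed cannot separate nuclei
#' once they merge into a quasi-continuous band of tissue, because the
#' distance ridge then follows the tube rather than individual cells), and
#' a minimum-area filter; returns sub-pixel centroids. A blank image
#' yields zero centroids, not an error.
#'
#' @param channel numeric matrix in [0, 1] (the nuclear stain).
#' @param blurSigma Gaussian blur sd, px.
#' @param minArea minimum object area after watershed, px^2.
#' @param watershedTolerance minimum intensity dip between two peaks for
#'   them to count as separate nuclei (intensity units).
#' @return data.frame with columns `x`, `y` (sub-pixel centroids) and
#'   `area`.
#' @export
segmentNuclei <- function(channel, blurSigma = 1, minArea = 5,
                          watershedTolerance = 0.02) {
  stopifnot(is.matrix(channel), length(channel) > 0)
  empty <- data.frame(x = numeric(0), y = numeric(0), area = numeric(0))
  img <- EBImage::Image(clip01(channel))
  bl <- EBImage::gblur(img, sigma = blurSigma)
  rng <- range(as.numeric(bl))
  if (diff(rng) < 1e-6) return(empty)
  th <- EBImage::otsu(bl, range = c(0, 1))
  bw <- bl > th
  if (!any(bw)) return(empty)
  lab <- EBImage::watershed(bl * bw, tolerance = watershedTolerance,
                            ext = 1)
  sizes <- tabulate(as.integer(lab))
  small <- which(sizes < minArea)
  if (length(small))
    lab <- EBImage::rmObjects(lab, small, reenumerate = TRUE)
  if (max(lab) == 0) return(empty)
  # centroids from each object's bright core: watershed regions also absorb
  # surrounding dimly stained tissue, which would drag an intensity-weighted
  # whole-object centroid off the nucleus
  labv <- as.integer(lab)
  blv <- as.numeric(bl)
  inobj <- labv > 0L
  peaks <- rep(-Inf, max(labv))
  pk <- tapply(blv[inobj], labv[inobj], max)
  peaks[as.integer(names(pk))] <- pk
  core <- inobj & blv > 0.5 * (peaks[pmax(labv, 1L)] + th)
  d <- dim(channel)
  xi <- ((seq_along(blv) - 1L) %% d[1]) + 1L
  yi <- ((seq_along(blv) - 1L) %/% d[1]) + 1L
  l <- labv[core]
  w <- blv[core] - th
  sw <- rowsum(w, l)
  cx <- rowsum(w * xi[core], l) / sw
  cy <- rowsum(w * yi[core], l) / sw
  sizes <- tabulate(labv)
  data.frame(x = as.numeric(cx), y = as.numeric(cy),
             area = sizes[as.integer(rownames(sw))])
}

#' Identify GFP-positive cells among segmented nuclei
#'
#' A nucleus is GFP+ when the mean GFP intensity in a small disk around its
#' centroid exceeds a robust background threshold: the 10th percentile of
#' the GFP channel (restricted to the tissue mask when one is supplied)
#' plus k times the MAD of the below-median pixels. Anchoring the
#' background on the dim tail keeps the threshold valid whatever the GFP+
#' fraction — a median-based estimate breaks down when most of the tissue
#' carries signal.
#' Restricting the background statistics to the tissue matters: the
#' fraction of empty canvas varies between images (longer, curvier guts
#' have proportionally more background), so a whole-image threshold drifts
#' with gut geometry and biases GFP calls between groups. Calling on
#' nucleus centroids rather than segmenting the GFP channel independently
#' avoids double counting.
#'
#' @param gfp numeric matrix, the GFP channel.
#' @param centroids data.frame with `x`, `y` as from [segmentNuclei()].
#' @param mask optional logical matrix of the tissue foreground used for
#'   the background statistics.
#' @param diskRadius sampling disk radius, px.
#' @param k MAD multiplier of the background threshold.
#' @return logical vector, one entry per centroid.
#' @export
segmentGFPCells <- function(gfp, centroids, mask = NULL, diskRadius = 3,
                            k = 5) {
  stopifnot(is.matrix(gfp), is.data.frame(centroids))
  if (!nrow(centroids)) return(logical(0))
  bgv <- if (is.null(mask)) gfp else gfp[mask]
  lower <- bgv[bgv <= median(bgv)]
  bg <- quantile(bgv, 0.1, names = FALSE) + k * mad(lower)
  r <- as.integer(ceiling(diskRadius))
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= diskRadius^2, ]
  nx <- nrow(gfp); ny <- ncol(gfp)
  vapply(seq_len(nrow(centroids)), function(i) {
    ix <- round(centroids$x[i]) + off$dx
    iy <- round(centroids$y[i]) + off$dy
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    mean(gfp[cbind(ix[ok], iy[ok])]) > bg
  }, logical(1))
}

#' Assign arc-length deciles to points
#'
#' Decile index is `floor(10 t)` for arc fraction `t`, with `t = 1` placed
#' in decile 9 (half-open bins, last bin closed). Indices are 0-based.
#'
#' @param t numeric vector of arc-length fractions in [0, 1].
#' @return list with `decile` (0-based integer per point) and `counts`
#'   (length-10 vector summing to `length(t)`).
#' @export
#' @examples
#' assignDeciles(c(0.05, 0.95, 1))$decile
assignDeciles <- function(t) {
  if (any(t < 0 | t > 1, na.rm = TRUE) || anyNA(t))
    stop("arc-length fractions must lie in [0, 1]")
  d <- pmin(floor(10 * t), 9L)
  list(decile = as.integer(d),
       counts = as.integer(tabulate(d + 1L, nbins = 10L)))
}

#' Quantify a gut image end to end
#'
#' Traces the axis, segments nuclei and GFP+ EECs, projects each centroid
#' onto the axis to obtain its arc-length fraction, and bins cells into the
#' ten equal-length deciles.
#'
#' @param image a [GutImage-class].
#' @param axis optional precomputed [traceAxis()] result.
#' @param genotype genotype label carried into the result.
#' @param ... further arguments passed to [traceAxis()].
#' @return a [GutQuantification-class].
#' @export
quantifyGut <- function(image, axis = NULL, genotype = "control", ...) {
  stopifnot(is(image, "GutImage"))
  if (is.null(axis)) axis <- traceAxis(image, ...)
  cen <- segmentNuclei(nuclearChannel(image))
  if (nrow(cen)) {
    if (!is.null(axis$mask)) {
      inmask <- axis$mask[cbind(pmin(nrow(axis$mask),
                                     pmax(1, round(cen$x))),
                                pmin(ncol(axis$mask),
                                     pmax(1, round(cen$y))))]
      cen <- cen[inmask, , drop = FALSE]
    }
    gfp <- segmentGFPCells(gfpChannel(image), cen, mask = axis$mask)
    t <- projectOnPath(cen$x, cen$y, axis$path, axis$arc)
  } else {
    gfp <- logical(0)
    t <- numeric(0)
  }
  dec <- assignDeciles(t)
  cells <- data.frame(x = cen$x, y = cen$y, t = t, decile = dec$decile,
                      gfp = gfp)
  gfpCounts <- as.integer(tabulate(cells$decile[cells$gfp] + 1L,
                                   nbins = 10L))
  new("GutQuantification", lengthPx = axis$lengthPx, cells = cells,
      decileCountsTotal = dec$counts, decileCountsGFP = gfpCounts,
      sex = image@sex, genotype = genotype, mating = image@mating)
}

# Arc-length fraction of the nearest path vertex for each point.
projectOnPath <- function(x, y, path, arc) {
  n <- nrow(path)
  L <- arc[length(arc)]
  step <- max(1L, floor(n / 600))
  idx <- unique(c(seq(1L, n, by = step), n))
  px <- path[idx, 1]; py <- path[idx, 2]; pa <- arc[idx]
  vapply(seq_along(x), function(i) {
    j <- which.min((px - x[i])^2 + (py - y[i])^2)
    min(1, max(0, pa[j] / L))
  }, numeric(1))
}
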
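#' Trace the gut axis between the marked endpoints
#'
#' Builds a tissue foreground mask (Gaussian blur, Otsu threshold,
#' morphological closing so that the nucleus-dense tube becomes a connected
#' region), then finds the geodesic path between the anterior and posterior
#' endpoints through that mask with a Dijkstra search whose edge costs
#' penalise departure from the medial axis (via the distance transform), so
#' the path follows the tube centre rather than hugging inner curves. The
#' returned length is the arc length of the smoothed path polyline.
#' `mode = "endpoint"` instead returns the straight-line endpoint distance
#' (the simpler reading of a "pixel distance between the defined limits").
#'
#' @param image a [GutImage-class].
#' @param mode `"geodesic"` (default) or `"endpoint"`.
#' @param blurSigma Gaussian blur sd used for masking, px.
#' @param closingRadius radius of the closing brush, px; should exceed the
#'   typical nucleus spacing.
#' @param ridgePenalty weight of the off-axis penalty (0 = pure shortest
#'   path).
#' @param smoothWindow running-mean window (odd, px) applied to the raw
#'   pixel path before measuring its length.
#' @param snapRadius maximum distance (px) an endpoint may be moved to reach
#'   the mask.
#' @return list with `lengthPx`, `path` (n x 2 matrix of x, y), `arc`
#'   (cumulative arc length along `path`), and `mask` (logical matrix).
#' @export
traceAxis <- function(image, mode = c("geodesic", "endpoint"),
                      blurSigma = 2, closingRadius = 9, ridgePenalty = 4,
                      smoothWindow = 15, snapRadius = 25) {
  stopifnot(is(image, "GutImage"))
  mode <- match.arg(mode)
  ep <- imageEndpoints(image)
  if (mode == "endpoint") {
    len <- sqrt(sum((ep[1, ] - ep[2, ])^2))
    path <- rbind(ep[1, ], ep[2, ])
    return(list(lengthPx = len, path = path, arc = c(0, len), mask = NULL))
  }
  mask <- tissueMask(nuclearChannel(image), blurSigma, closingRadius)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  dm <- matrix(as.numeric(dm), nrow(mask), ncol(mask))
  dmax <- max(dm)
  if (dmax <= 0) stop("no tissue foreground found")
  w <- 1 + ridgePenalty * (1 - dm / dmax)^2
  w[!mask] <- NA_real_

  a <- snapToMask(ep[1, ], mask, snapRadius)
  b <- snapToMask(ep[2, ], mask, snapRadius)
  res <- .grid_geodesic(w, a, b)
  if (identical(res$cost, -1))
    stop("endpoints are not connected through the tissue foreground")
  path <- res$path
  sm <- smoothPath(path, smoothWindow)
  seg <- sqrt(rowSums((sm[-1, , drop = FALSE] -
                         sm[-nrow(sm), , drop = FALSE])^2))
  list(lengthPx = sum(seg), path = sm, arc = c(0, cumsum(seg)), mask = mask)
}

# Foreground mask: blur, Otsu on the blurred image, then closing to merge
# the nucleus blobs into a connected tube.
tissueMask <- function(channel, blurSigma = 2, closingRadius = 9) {
  img <- EBImage::Image(clip01(channel))
  bl <- EBImage::gblur(img, sigma = blurSigma)
  th <- EBImage::otsu(bl, range = c(0, 1))
  fg <- bl > th
  br <- EBImage::makeBrush(2L * as.integer(closingRadius) + 1L, "disc")
  cl <- EBImage::closing(fg, br)
  matrix(as.logical(cl), nrow(channel), ncol(channel))
}

snapToMask <- function(pt, mask, snapRadius) {
  x <- round(pt[1]); y <- round(pt[2])
  nx <- nrow(mask); ny <- ncol(mask)
  x <- min(max(x, 1), nx); y <- min(max(y, 1), ny)
  if (mask[x, y]) return(c(x, y))
  r <- as.integer(ceiling(snapRadius))
  ix <- max(1, x - r):min(nx, x + r)
  iy <- max(1, y - r):min(ny, y + r)
  sub <- mask[ix, iy, drop = FALSE]
  if (!any(sub)) stop("endpoint is not near any tissue foreground")
  idx <- which(sub, arr.ind = TRUE)
  d2 <- (ix[idx[, 1]] - pt[1])^2 + (iy[idx[, 2]] - pt[2])^2
  if (min(d2) > snapRadius^2)
    stop("endpoint is not near any tissue foreground")
  k <- which.min(d2)
  c(ix[idx[k, 1]], iy[idx[k, 2]])
}

# Running-mean smoothing of a pixel path; endpoints are preserved.
smoothPath <- function(path, window) {
  n <- nrow(path)
  if (window < 3 || n < window) return(path)
  if (window %% 2 == 0) window <- window + 1
  kern <- rep(1 / window, window)
  sx <- stats::filter(path[, 1], kern, sides = 2)
  sy <- stats::filter(path[, 2], kern, sides = 2)
  h <- (window - 1) / 2
  out <- cbind(as.numeric(sx), as.numeric(sy))
  out[seq_len(h), ] <- path[seq_len(h), ]
  out[(n - h + 1):n, ] <- path[(n - h + 1):n, ]
  out
}
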
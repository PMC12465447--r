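#' 3D Gaussian filter with anisotropic voxel spacing
#'
#' Separable Gaussian smoothing of an intensity volume. The physical
#' sigma (in micrometres) is converted to a per-axis sigma in voxels
#' using the voxel spacing, so anisotropic stacks (e.g. 0.3 um optical
#' sections vs 0.1 um pixels) are smoothed isotropically in physical
#' space. Edges use nearest (replicate) padding, so a constant volume is
#' unchanged and interior signal is conserved.
#'
#' @param vol 3D numeric array (z, y, x).
#' @param spacing numeric length-3 (z, y, x) voxel size in um.
#' @param sigmaUm physical Gaussian sigma in um, default 0.15.
#' @return smoothed array of the same dimensions.
#' @export
gaussianBlur3d <- function(vol, spacing, sigmaUm = 0.15) {
  stopifnot(length(dim(vol)) == 3L, length(spacing) == 3L, all(spacing > 0),
            sigmaUm >= 0)
  if (sigmaUm == 0) return(vol)
  for (axis in 1:3) {
    sig <- sigmaUm / spacing[axis]
    if (sig < 0.05) next
    r <- max(1L, ceiling(3 * sig))
    k <- exp(-((-r:r)^2) / (2 * sig^2))
    k <- k / sum(k)
    vol <- convolveAxisNearest(vol, k, axis)
  }
  vol
}

# 1D convolution along one axis of a 3D array with replicate padding;
# kernel length 2r+1, applied as a sum of shifted slabs.
convolveAxisNearest <- function(vol, kernel, axis) {
  d <- dim(vol)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  idx <- function(shift) pmin(pmax(seq_len(n) + shift, 1L), n)
  for (t in seq_along(kernel)) {
    shift <- t - r - 1L
    sel <- idx(shift)
    shifted <- switch(axis,
                      vol[sel, , , drop = FALSE],
                      vol[, sel, , drop = FALSE],
                      vol[, , sel, drop = FALSE])
    out <- out + kernel[t] * shifted
  }
  out
}

#' Otsu intensity threshold
#'
#' Histogram-based threshold maximising between-class variance; used as
#' the default threshold rule for spot segmentation.
#'
#' @param x numeric vector or array of intensities.
#' @param nbins histogram bins, default 256.
#' @return threshold value.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[nbins]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  # histogram gaps create a plateau of maximisers; take its midpoint
  idx <- which(sigmaB >= max(sigmaB) - 1e-12)
  mids[round(mean(range(idx)))]
}

#' 3D spot segmentation
#'
#' Thresholds the (typically pre-blurred) volume, groups above-threshold
#' voxels by 26-connectivity, discards components smaller than
#' `minSpotVoxels`, and returns intensity-weighted centroids in physical
#' micrometres (voxel centre of the first voxel at 0 on each axis).
#'
#' @param vol 3D numeric array (z, y, x).
#' @param spacing numeric length-3 (z, y, x) voxel size in um.
#' @param threshold threshold rule: `list(method = "otsu")` (default),
#'   `list(method = "quantile", value = q)`, or
#'   `list(method = "absolute", value = t)`.
#' @param minSpotVoxels minimum component size, default 4.
#' @return data.frame with one row per spot: centroid_z/y/x (um), volume
#'   (voxels), total_intensity; ordered by decreasing total intensity.
#' @export
segmentSpots <- function(vol, spacing, threshold = list(method = "otsu"),
                         minSpotVoxels = 4L) {
  stopifnot(length(dim(vol)) == 3L, length(spacing) == 3L, all(spacing > 0))
  thr <- switch(threshold$method,
                otsu = otsuThreshold(vol),
                quantile = quantile(vol, threshold$value, names = FALSE),
                absolute = threshold$value,
                stop("unknown threshold method: ", threshold$method))
  d <- dim(vol)
  fg <- which(vol > thr)
  empty <- data.frame(centroid_z = numeric(0), centroid_y = numeric(0),
                      centroid_x = numeric(0), volume = integer(0),
                      total_intensity = numeric(0))
  if (length(fg) == 0L) return(empty)
  lab <- integer(length(vol))
  inFg <- logical(length(vol)); inFg[fg] <- TRUE
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  # 26-neighbourhood linear-index offsets (validity checked per coordinate)
  nbr <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nbr <- nbr[!(nbr$dz == 0 & nbr$dy == 0 & nbr$dx == 0), ]
  comp <- 0L
  spots <- list()
  for (seed in fg) {
    if (lab[seed] != 0L) next
    comp <- comp + 1L
    stack <- seed
    lab[seed] <- comp
    members <- integer(0)
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      c0 <- cur - 1L
      z <- c0 %% nz; rest <- c0 %/% nz
      y <- rest %% ny; x <- rest %/% ny
      zz <- z + nbr$dz; yy <- y + nbr$dy; xx <- x + nbr$dx
      okn <- zz >= 0 & zz < nz & yy >= 0 & yy < ny & xx >= 0 & xx < nx
      lin <- (xx[okn] * ny + yy[okn]) * nz + zz[okn] + 1L
      lin <- lin[inFg[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- comp
        stack <- c(stack, lin)
      }
    }
    if (length(members) < minSpotVoxels) next
    c0 <- members - 1L
    z <- c0 %% nz; rest <- c0 %/% nz
    y <- rest %% ny; x <- rest %/% ny
    wts <- vol[members]
    tw <- sum(wts)
    spots[[length(spots) + 1L]] <- data.frame(
      centroid_z = sum(z * wts) / tw * spacing[1],
      centroid_y = sum(y * wts) / tw * spacing[2],
      centroid_x = sum(x * wts) / tw * spacing[3],
      volume = length(members), total_intensity = tw)
  }
  if (length(spots) == 0L) return(empty)
  out <- do.call(rbind, spots)
  out[order(-out$total_intensity), , drop = FALSE]
}

#' Euclidean distance between two segmented spots
#'
#' @param a,b single-row data.frames (or lists) with centroid_z/y/x in um.
#' @return distance in um.
#' @export
spotDistance <- function(a, b) {
  sqrt((a$centroid_z - b$centroid_z)^2 +
         (a$centroid_y - b$centroid_y)^2 +
         (a$centroid_x - b$centroid_x)^2)
}

#' Neighbour-normalised fluorescence
#'
#' Target cell mean intensity divided by the mean of exactly three nearby
#' non-electroporated neighbour cells.
#'
#' @param targetMean mean intensity of the target (electroporated) cell.
#' @param neighborMeans numeric vector of exactly three neighbour means,
#'   all positive.
#' @return normalised ratio.
#' @export
normalizeFluorescence <- function(targetMean, neighborMeans) {
  if (length(neighborMeans) != 3L)
    stop("exactly three neighbour intensities are required, got ",
         length(neighborMeans))
  if (any(is.na(neighborMeans)) || any(neighborMeans <= 0))
    stop("neighbour intensities must all be positive")
  m <- mean(neighborMeans)
  if (m == 0) stop("zero neighbour mean")
  targetMean / m
}

#' Read a multi-page TIFF stack as a 3D volume
#'
#' Pages become z-planes; the caller supplies the physical voxel spacing.
#'
#' @param path TIFF path.
#' @return 3D array (z, y, x) of intensities.
#' @export
readVolumeTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  vol <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) vol[i, , ] <- pages[[i]]
  vol
}

#' Paired probe distance from a two-channel volume
#'
#' Blurs each channel, segments spots, takes the brightest spot per
#' channel (logging when more than the expected number of signals is
#' present), and returns the Euclidean probe distance.
#'
#' @param volA,volB 3D arrays for the two probe channels.
#' @param spacing voxel spacing (z, y, x) in um.
#' @param sigmaUm blur sigma in um, default 0.15.
#' @param threshold threshold rule, see [segmentSpots()].
#' @param minSpotVoxels minimum spot size, default 4.
#' @param expectedSpots expected signals per channel, default 2 (two
#'   alleles).
#' @return list with `distance` (um, `NA` when a channel has no spot),
#'   `spots` (per-channel spot tables), `multiSpot` (logical per channel).
#' @export
probeDistance <- function(volA, volB, spacing, sigmaUm = 0.15,
                          threshold = list(method = "otsu"),
                          minSpotVoxels = 4L, expectedSpots = 2L) {
  chans <- list(A = volA, B = volB)
  spots <- lapply(chans, function(v) {
    segmentSpots(gaussianBlur3d(v, spacing, sigmaUm), spacing,
                 threshold = threshold, minSpotVoxels = minSpotVoxels)
  })
  multi <- vapply(spots, function(s) nrow(s) > expectedSpots, TRUE)
  if (any(multi))
    message("channel(s) with more than ", expectedSpots,
            " spots: brightest used")
  if (any(vapply(spots, nrow, 0L) == 0L))
    return(list(distance = NA_real_, spots = spots, multiSpot = multi))
  list(distance = spotDistance(spots[[1]][1, ], spots[[2]][1, ]),
       spots = spots, multiSpot = multi)
}
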
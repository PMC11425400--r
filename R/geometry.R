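## Polyline geometry in physical units, and the rasterization helpers the
## simulator uses. Pixel (i, j) (1-based row, col) has its centre at
## physical (x, y) = ((j - 1) * pitch, (i - 1) * pitch): 0-based indices
## times the pixel pitch.

.polylineLength <- function(vertices) {
  d <- diff(vertices)
  sum(sqrt(rowSums(d^2)))
}

## Sample positions along a polyline at a fixed arclength step, always
## including the final vertex so the profile spans the full drawn line.
.samplePolyline <- function(vertices, step) {
  segs <- diff(vertices)
  segLen <- sqrt(rowSums(segs^2))
  total <- sum(segLen)
  s <- seq(0, total, by = step)
  if (total - s[length(s)] > 1e-9) s <- c(s, total)
  cumLen <- c(0, cumsum(segLen))
  seg <- pmin(findInterval(s, cumLen, rightmost.closed = TRUE),
              nrow(vertices) - 1L)
  frac <- ifelse(segLen[seg] > 0, (s - cumLen[seg]) / segLen[seg], 0)
  cbind(x = vertices[seg, 1] + frac * segs[seg, 1],
        y = vertices[seg, 2] + frac * segs[seg, 2],
        s = s)
}

## Bilinear interpolation of a matrix at fractional pixel coordinates
## (1-based row/col). Callers guarantee in-bounds positions.
.bilinear <- function(img, row, col) {
  r0 <- pmin(pmax(floor(row), 1L), nrow(img) - 1L)
  c0 <- pmin(pmax(floor(col), 1L), ncol(img) - 1L)
  fr <- row - r0
  fc <- col - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

## Distance-to-centerline and arclength-of-projection maps for a vessel on
## a pixel grid. Returns, per pixel, the distance (mm) to the nearest
## point of the polyline and the arclength (mm) of that point.
.vesselMaps <- function(vertices, pitch, rows, cols) {
  px <- matrix(rep((seq_len(cols) - 1) * pitch, each = rows), rows, cols)
  py <- matrix(rep((seq_len(rows) - 1) * pitch, times = cols), rows, cols)
  bestD2 <- matrix(Inf, rows, cols)
  bestS <- matrix(0, rows, cols)
  cum <- 0
  for (k in seq_len(nrow(vertices) - 1L)) {
    x1 <- vertices[k, 1]; y1 <- vertices[k, 2]
    dx <- vertices[k + 1L, 1] - x1; dy <- vertices[k + 1L, 2] - y1
    len2 <- dx * dx + dy * dy
    len <- sqrt(len2)
    t <- if (len2 > 0) ((px - x1) * dx + (py - y1) * dy) / len2 else
      matrix(0, rows, cols)
    t <- pmin(pmax(t, 0), 1)
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    upd <- d2 < bestD2
    bestD2[upd] <- d2[upd]
    bestS[upd] <- cum + t[upd] * len
    cum <- cum + len
  }
  list(dist = sqrt(bestD2), s = bestS)
}

## Transverse coverage of a ridge of the given full width: fraction of the
## pixel (approximated along the normal direction) inside the ridge. The
## linear edge ramp makes the half-maximum crossings of an unblurred ridge
## profile fall exactly at +/- width/2.
.ridgeCoverage <- function(dist, width, pitch) {
  pmin(pmax((width / 2 - dist) / pitch + 0.5, 0), 1)
}

## Separable Gaussian blur with a normalized kernel and circular boundary
## (preserves total intensity). sigma is in pixels.
.gaussianBlur <- function(img, sigmaPx) {
  if (sigmaPx <= 0) return(img)
  r <- ceiling(4 * sigmaPx)
  maxR <- (min(dim(img)) - 1L) %/% 2L
  r <- min(r, maxR)
  if (r < 1L) return(img)
  k <- dnorm(seq(-r, r), sd = sigmaPx)
  k <- k / sum(k)
  EBImage::filter2(img, outer(k, k), boundary = "circular")
}

## Poisson shot noise (photon units = counts / gain) plus Gaussian read
## noise, clipped to the camera range and rounded to integer counts.
.applySensorNoise <- function(signal, camera) {
  photons <- pmax(signal, 0) / camera@gain
  noisy <- rpois(length(photons), photons) * camera@gain +
    rnorm(length(photons), sd = camera@readNoiseSd)
  out <- round(pmin(pmax(noisy, 0), 2^camera@bitDepth - 1))
  array(out, dim(signal))
}
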
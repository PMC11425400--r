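## Shared peak engine: local maxima, topographic prominence, FWHM.
## Used by both the cross-section (space) and bolus (time) detectors.

## Leftmost sample of each interior plateau that is a strict local maximum
## of the run-length-encoded signal.
.localMaxima <- function(y) {
  r <- rle(y)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  j <- 2:(k - 1L)
  peakRuns <- j[r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]]
  starts[peakRuns]
}

## Topographic prominence of the peak at index i: height above the higher
## of the two key saddles, where each saddle is the minimum between the
## peak and the nearest strictly higher sample on that side (or the signal
## edge when no higher sample exists).
.prominenceAt <- function(y, i) {
  n <- length(y)
  left <- if (i == 1L) y[1L] else {
    higher <- which(y[seq_len(i - 1L)] > y[i])
    from <- if (length(higher)) max(higher) else 1L
    min(y[from:i])
  }
  right <- if (i == n) y[n] else {
    higher <- which(y[(i + 1L):n] > y[i])
    to <- if (length(higher)) i + min(higher) else n
    min(y[i:to])
  }
  y[i] - max(left, right)
}

## Half-maximum width around the apex at index i, by linear interpolation
## of the crossings of `ref` walking outward from the apex. Returns NA when
## a crossing is not reached before the profile edge or before the terrain
## rises above the apex (an adjacent higher peak past a saddle above the
## reference level).
.fwhmAt <- function(x, y, i, ref) {
  apex <- y[i]
  cross <- function(step) {
    j <- i
    repeat {
      k <- j + step
      if (k < 1L || k > length(y)) return(NA_real_)
      if (y[k] <= ref) {
        frac <- (y[j] - ref) / (y[j] - y[k])
        return(x[j] + frac * (x[k] - x[j]))
      }
      if (y[k] > apex) return(NA_real_)  # higher terrain: unresolved overlap
      j <- k
    }
  }
  xl <- cross(-1L)
  xr <- cross(+1L)
  if (is.na(xl) || is.na(xr)) NA_real_ else xr - xl
}

## Full detection: candidate maxima -> prominence threshold -> greedy
## minimum-separation pruning (taller peaks first) -> FWHM per survivor.
## `x` carries the physical axis (mm or s); `refLevel` selects the FWHM
## reference: half of peak height, or height - prominence/2.
.detectPeaks <- function(x, y, minProminence = 0.05, minSeparation = 0.3,
                         refLevel = c("height", "prominence")) {
  refLevel <- match.arg(refLevel)
  empty <- data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0), fwhm = numeric(0),
                      index = integer(0))
  idx <- .localMaxima(y)
  if (!length(idx)) return(empty)
  prom <- vapply(idx, function(i) .prominenceAt(y, i), numeric(1))
  keep <- prom >= minProminence & prom > 0
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx)) return(empty)
  ord <- order(y[idx], prom, decreasing = TRUE)
  kept <- logical(length(idx))
  for (o in ord) {
    if (any(kept & abs(x[idx] - x[idx[o]]) < minSeparation)) next
    kept[o] <- TRUE
  }
  idx <- idx[kept]; prom <- prom[kept]
  ord <- order(idx)
  idx <- idx[ord]; prom <- prom[ord]
  ref <- switch(refLevel,
                height = y[idx] / 2,
                prominence = y[idx] - prom / 2)
  fw <- vapply(seq_along(idx), function(k)
    .fwhmAt(x, y, idx[k], ref[k]), numeric(1))
  data.frame(position = x[idx], height = y[idx], prominence = prom,
             fwhm = fw, index = idx)
}
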
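## Orthogonal periodized discrete wavelet transform and empirical-Bayes
## posterior-median shrinkage, applied row-wise to pixel x time matrices.
## No wavelet package ships with the dependency set, so the filter bank is
## implemented here. Filter coefficients are the published symlet-8
## orthonormal quadrature mirror pair (16 taps, 8 vanishing moments).

.SYM8_DEC_LO <- c(
  -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
   0.007607487324917605,  -0.1432942383508097,   -0.061273359067658524,
   0.4813596512583722,     0.7771857517005235,    0.3644418948353314,
  -0.05194583810770904,   -0.027219029917056003,  0.049137179673607506,
   0.003808752013890615,  -0.01495225833704823,  -0.0003029205147213668,
   0.0018899503327594609)

## High-pass by the alternating-sign (QMF) relation g[k] = (-1)^k h[L-1-k].
.qmfHighPass <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

.WAVELET_FILTERS <- list(
  sym8 = list(lo = .SYM8_DEC_LO, hi = .qmfHighPass(.SYM8_DEC_LO))
)

## One analysis level on all rows at once: circular convolution with the
## analysis pair, downsampled by 2. ncol(X) must be even.
.dwtStep <- function(X, h, g) {
  N <- ncol(X)
  K <- N %/% 2L
  A <- matrix(0, nrow(X), K)
  D <- matrix(0, nrow(X), K)
  base <- (seq_len(K) - 1L) * 2L
  for (m in seq_along(h)) {
    idx <- ((base + (m - 1L)) %% N) + 1L
    A <- A + h[m] * X[, idx, drop = FALSE]
    D <- D + g[m] * X[, idx, drop = FALSE]
  }
  list(A = A, D = D)
}

## Adjoint synthesis (exact inverse for an orthonormal periodized bank).
.idwtStep <- function(A, D, h, g) {
  K <- ncol(A)
  N <- 2L * K
  X <- matrix(0, nrow(A), N)
  base <- (seq_len(K) - 1L) * 2L
  for (m in seq_along(h)) {
    idx <- ((base + (m - 1L)) %% N) + 1L
    X[, idx] <- X[, idx] + h[m] * A + g[m] * D
  }
  X
}

## Effective decomposition depth for series of length n: the requested
## level, capped at floor(log2(n)) - 1 so at least two approximation
## coefficients remain.
.effectiveLevel <- function(n, level) {
  max(1L, min(as.integer(level), as.integer(floor(log2(n))) - 1L))
}

## Full multi-level analysis of the rows of X. Rows are reflect-padded on
## the right to the next multiple of 2^level and then mirrored in full, so
## the periodized bank sees a circularly continuous symmetric extension
## (no wrap discontinuity at either junction); the original length is kept
## for cropping after synthesis.
.dwt <- function(X, level, family = "sym8") {
  f <- .WAVELET_FILTERS[[family]]
  n <- ncol(X)
  block <- 2L^level
  Npad <- block * ceiling(n / block)
  if (Npad > n) {
    padLen <- Npad - n
    stopifnot(padLen <= n - 1L)  # guaranteed by the level cap
    X <- cbind(X, X[, n - seq_len(padLen), drop = FALSE])
  }
  X <- cbind(X, X[, ncol(X):1, drop = FALSE])
  D <- vector("list", level)
  A <- X
  for (j in seq_len(level)) {
    s <- .dwtStep(A, f$lo, f$hi)
    A <- s$A
    D[[j]] <- s$D
  }
  list(A = A, D = D, n = n, family = family)
}

## Synthesis from (possibly modified) coefficients, cropped to length n.
.idwt <- function(A, D, n, family = "sym8") {
  f <- .WAVELET_FILTERS[[family]]
  for (j in rev(seq_along(D)))
    A <- .idwtStep(A, D[[j]], f$lo, f$hi)
  A[, seq_len(n), drop = FALSE]
}

## ---- Empirical-Bayes posterior-median shrinkage ------------------------
## Spike-and-Laplace prior on each (standardized) wavelet coefficient:
## mu ~ (1 - w) delta_0 + w * Laplace(a), observation x ~ N(mu, 1).
## The mixing weight w is estimated per detail level by marginal maximum
## likelihood; shrinkage is the posterior median (zero for small |x|).

## beta(x) = g(x)/phi(x) - 1 where g is the marginal density under the
## Laplace component; written with Mills ratios for numerical stability.
.betaLaplace <- function(x, a = 0.5) {
  x <- abs(x)
  xpa <- x + a
  xma <- x - a
  rat1 <- ifelse(xpa > 35, 1 / xpa, pnorm(-xpa) / dnorm(xpa))
  rat2 <- ifelse(xma > 35, .Machine$double.xmax / 2,
                 ifelse(xma < -35, 1 / pmax(-xma, 1), pnorm(xma) / dnorm(xma)))
  (a / 2) * (rat1 + rat2) - 1
}

## Marginal-ML mixing weight for one coefficient vector (unit noise scale).
## The log-likelihood l(w) = sum log(1 + w beta_i) is concave with a
## monotone derivative, so the optimum is at a bound or at the root of the
## derivative.
.ebWeight <- function(x, a = 0.5) {
  beta <- pmin(.betaLaplace(x, a), 1e100)
  deriv <- function(w) sum(beta / (1 + w * beta))
  lo <- 1e-6
  if (deriv(1) >= 0) return(1)
  if (deriv(lo) <= 0) return(lo)
  uniroot(deriv, c(lo, 1), tol = 1e-9)$root
}

## Posterior median under the spike-and-Laplace prior (unit noise scale).
## Antisymmetric in x; exactly zero below the implied threshold.
.postMedLaplace <- function(x, w, a = 0.5) {
  sx <- sign(x)
  ax <- abs(x)
  xma <- ax - a
  zz <- (1 / a) * dnorm(xma) * (1 / w + .betaLaplace(ax, a))
  zz[!is.finite(zz) | xma > 25] <- 0.5
  mucor <- qnorm(pmin(zz, 1))
  sx * pmax(0, xma - mucor)
}

## Row-wise wavelet machinery shared by denoising and the residual
## transform. For each row: estimate one noise scale from the finest
## detail level (MAD / 0.6745, level-independent), shrink every detail
## level by the posterior median, and return both the shrunken detail set
## and the approximation. Rows with zero noise estimate keep their details
## unshrunken (nothing to denoise against).
.shrinkDetails <- function(dec, a = 0.5) {
  nr <- nrow(dec$A)
  d1 <- dec$D[[1L]]
  sigma <- apply(d1, 1L, function(v) median(abs(v))) / 0.6745
  Ds <- lapply(dec$D, function(Dj) {
    out <- Dj
    for (r in seq_len(nr)) {
      if (sigma[r] <= 0 || !is.finite(sigma[r])) next
      z <- Dj[r, ] / sigma[r]
      w <- .ebWeight(z)
      out[r, ] <- sigma[r] * .postMedLaplace(z, w)
    }
    out
  })
  list(D = Ds, sigma = sigma)
}
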
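## Independent brute-force oracles and shared fixtures.  The oracles use
## direct summation / exhaustive scans only, never the package's FFT paths.

## Sliding-window background stats by direct summation over Mo.
bruteLocalStats <- function(X, masks) {
  n <- nrow(X)
  b <- boxSize(masks)
  moIdx <- which(outerMask(masks) == 1, arr.ind = TRUE)
  mu <- matrix(NA_real_, n, n)
  sigma <- matrix(NA_real_, n, n)
  for (r0 in 0:(n - b)) for (c0 in 0:(n - b)) {
    vals <- X[cbind(moIdx[, 1L] + r0, moIdx[, 2L] + c0)]
    m <- mean(vals)
    mu[r0 + 1L, c0 + 1L] <- m
    sigma[r0 + 1L, c0 + 1L] <- sqrt(mean((vals - m)^2))
  }
  list(mu = mu, sigma = sigma)
}

## Per-position log probability ratio and similarity by direct summation.
bruteSimilarity <- function(X, template, stats, masks, logE = NULL) {
  n <- nrow(X)
  b <- boxSize(masks)
  if (is.null(logE)) logE <- sum(template^2) / (2 * nInner(masks))
  sA <- sum(template)
  sA2 <- sum(template^2)
  S <- matrix(NA_real_, n, n)
  for (r0 in 0:(n - b)) for (c0 in 0:(n - b)) {
    mu <- stats@mu[r0 + 1L, c0 + 1L]
    sg <- stats@sigma[r0 + 1L, c0 + 1L]
    if (!stats@valid[r0 + 1L, c0 + 1L]) next
    cc <- sum(X[(r0 + 1L):(r0 + b), (c0 + 1L):(c0 + b)] * template)
    expo <- cc / sg - (mu / sg) * sA - 0.5 * sA2
    S[r0 + 1L, c0 + 1L] <- expm1(expo) / expm1(logE)
  }
  S
}

## Exhaustive 4-neighbour local-maximum scan.
brutePeaks <- function(map, threshold) {
  out <- data.frame(row = integer(0), col = integer(0), value = numeric(0))
  for (i in 2:(nrow(map) - 1L)) for (j in 2:(ncol(map) - 1L)) {
    v <- map[i, j]
    if (v > threshold && v > -1e29 &&
        v > map[i - 1L, j] && v > map[i + 1L, j] &&
        v > map[i, j - 1L] && v > map[i, j + 1L])
      out <- rbind(out, data.frame(row = i, col = j, value = v))
  }
  out
}

## Maximum-cardinality bipartite matching under a distance cap, by
## exhaustive recursion (for small instances only).
bruteMaxMatching <- function(picks, truth, radius) {
  nP <- nrow(picks); nT <- nrow(truth)
  if (nP == 0L || nT == 0L) return(0L)
  ok <- outer(seq_len(nP), seq_len(nT), function(i, j) {
    sqrt((picks$x[i] - truth$x[j])^2 + (picks$y[i] - truth$y[j])^2) <= radius
  })
  best <- 0L
  recurse <- function(i, usedT, count) {
    if (count + (nP - i + 1L) <= best) return()
    if (i > nP) { best <<- max(best, count); return() }
    for (j in which(ok[i, ] & !usedT)) {
      usedT[j] <- TRUE
      recurse(i + 1L, usedT, count + 1L)
      usedT[j] <- FALSE
    }
    recurse(i + 1L, usedT, count)
  }
  recurse(1L, logical(nT), 0L)
  best
}

## Radial spectral power beyond a resolution cutoff.
outOfBandPower <- function(img, cutoff, pixelSize) {
  n <- nrow(img)
  k <- 0:(n - 1L)
  kk <- ifelse(k <= n / 2, k, k - n) / (n * pixelSize)
  f <- sqrt(outer(kk^2, kk^2, "+"))
  ft <- stats::fft(img)
  sum(Mod(ft[f > 1 / cutoff])^2)
}

## The documented synthetic study conditions: a mid-size (84 Angstrom)
## particle sampled at 3 A/px, disc + rod analytic templates, SNR 2.
studyConditions <- function() {
  ps <- 3; box <- 40L; R <- 14
  list(pixelSize = ps, boxSize = box, maskRadius = R,
       diameter = 2 * R * ps, snr = 2,
       raw = list(discTemplate(box, 0.7 * R),
                  rodTemplate(box, 1.8 * R, 0.7 * R)))
}

## Picking templates scaled to the planted particle contrast (class
## averages of normalised particles carry the particle's own amplitude).
studyTemplates <- function(sc = studyConditions()) {
  templateSet(lapply(sc$raw, function(a) a * sqrt(sc$snr)),
              pixelSize = sc$pixelSize)
}

## Smallest angular distance modulo a symmetry period (degrees).
angleDiff <- function(a, b, period = 180) {
  d <- (a - b) %% period
  pmin(d, period - d)
}
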
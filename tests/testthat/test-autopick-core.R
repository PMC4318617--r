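test_that("noise padding preserves the original region and its statistics", {
  set.seed(9)
  sq <- micrograph(matrix(rnorm(64 * 64), 64, 64))
  p <- padToSquare(sq, seed = 0)
  expect_identical(pixels(p$micrograph), pixels(sq))
  expect_equal(p$offset, c(0L, 0L))
  rect <- micrograph(matrix(rnorm(64 * 48, mean = 5, sd = 3), 64, 48))
  p2 <- padToSquare(rect, seed = 0)
  expect_equal(dim(p2$micrograph), c(64L, 64L))
  expect_identical(pixels(p2$micrograph)[1:64, 1:48], pixels(rect))
  # padded area (64 x 16 = 1024 px) matches global mean/sd within 5%
  pad <- pixels(p2$micrograph)[, 49:64]
  expect_lt(abs(mean(pad) - mean(pixels(rect))) / abs(mean(pixels(rect))),
            0.05)
  expect_lt(abs(sd(pad) - sd(pixels(rect))) / sd(pixels(rect)), 0.05)
  # identical seed, identical padding
  expect_identical(pixels(padToSquare(rect, seed = 0)$micrograph),
                   pixels(p2$micrograph))
})

test_that("the expected probability ratio follows its closed form", {
  m <- makeMasks(16, 5)
  expect_identical(expectedRatio(matrix(0, 16, 16), m), 1)
  # sum A^2 = 2 |Mi| gives exactly e
  a <- matrix(0, 16, 16)
  a[innerMask(m) == 1] <- sqrt(2)
  expect_equal(expectedRatio(a, m), exp(1), tolerance = 1e-12)
  set.seed(12)
  b <- matrix(rnorm(256, sd = 0.3), 16, 16) * innerMask(m)
  expect_equal(expectedRatio(b, m), exp(sum(b^2) / (2 * nInner(m))),
               tolerance = 1e-10)
})

test_that("FFT similarity maps equal the direct per-position evaluation", {
  set.seed(30)
  m <- makeMasks(12, 4)
  X <- matrix(rnorm(32 * 32), 32, 32)
  tpl <- lowpassStrict(discTemplate(12, 3.5) * 0.8, 4, 2) * innerMask(m)
  st <- localBackgroundStats(X, m)
  S <- similarityMap(X, tpl, st, m)
  ref <- bruteSimilarity(X, tpl, st, m)
  ok <- !is.na(ref)
  expect_lt(max(abs(S[ok] - ref[ok])), 1e-6)
  # sentinel everywhere else
  expect_true(all(S[!ok] < -1e29))
  # an all-zero template carries no signal
  expect_error(similarityMap(X, matrix(0, 12, 12), st, m), "no signal")
})

test_that("a planted normalised signal is the global similarity argmax", {
  set.seed(31)
  m <- makeMasks(12, 4)
  tpl <- discTemplate(12, 3.5) * innerMask(m)
  X <- matrix(rnorm(48 * 48), 48, 48)
  st0 <- localBackgroundStats(X, m)
  r0 <- 17L; c0 <- 23L   # 1-based corner of the planted box
  mu <- st0@mu[r0, c0]; sg <- st0@sigma[r0, c0]
  # make (X - mu)/sigma equal the template exactly over the planted box
  X[r0:(r0 + 11L), c0:(c0 + 11L)] <- mu + sg * tpl
  st <- localBackgroundStats(X, m)
  S <- similarityMap(X, tpl, st, m)
  best <- which(S == max(S), arr.ind = TRUE)
  expect_lt(sqrt((best[1L] - r0)^2 + (best[2L] - c0)^2), 2)
  expect_gt(max(S), 0)
})

test_that("local maxima match the exhaustive 4-neighbour scan", {
  # one smooth bump above threshold
  g <- outer(1:21, 1:21, function(r, c)
    0.8 * exp(-((r - 11)^2 + (c - 11)^2) / 8))
  pk <- findLocalMaxima(g, 0.3)
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$row, pk$col), c(11L, 11L))
  # a flat grid has no strict local maxima
  expect_equal(nrow(findLocalMaxima(matrix(1, 15, 15), 0)), 0L)
  # random grids: identical to the brute-force scan
  for (sd in 1:3) {
    set.seed(sd)
    r <- matrix(rnorm(30 * 30), 30, 30)
    got <- findLocalMaxima(r, 0.5)
    ref <- brutePeaks(r, 0.5)
    ref <- ref[order(ref$row, ref$col), ]
    expect_equal(got$row, ref$row)
    expect_equal(got$col, ref$col)
    expect_equal(got$value, ref$value, tolerance = 1e-12)
  }
})

test_that("distance pruning keeps cluster maxima recursively", {
  d <- 10
  # two close peaks: only the higher survives
  p2 <- data.frame(row = c(10, 10), col = c(10, 15),
                   value = c(0.5, 0.4))
  expect_equal(prunePeaks(p2, d)$value, 0.5)
  # three collinear peaks spaced 0.8 d: the middle one is suppressed by
  # the best, the third survives at 1.6 d from the best
  p3 <- data.frame(row = c(10, 10, 10), col = c(10, 18, 26),
                   value = c(0.9, 0.8, 0.7))
  expect_equal(sort(prunePeaks(p3, d)$value), c(0.7, 0.9))
  # property: pairwise distances >= d and the global max survives
  for (sd in 1:5) {
    set.seed(sd)
    n <- 40L
    pp <- data.frame(row = runif(n, 1, 60), col = runif(n, 1, 60),
                     value = runif(n))
    kept <- prunePeaks(pp, d)
    expect_true(max(pp$value) %in% kept$value)
    if (nrow(kept) > 1L)
      expect_true(all(dist(cbind(kept$row, kept$col)) >= d))
  }
})

test_that("similarity and picks are invariant to affine intensity changes", {
  sc <- studyConditions()
  sim <- simulateMicrograph(shape = c(256, 256), pixelSize = sc$pixelSize,
                            nParticles = 4, templates = sc$raw,
                            boxSize = sc$boxSize,
                            maskRadius = sc$maskRadius, snr = sc$snr,
                            minDistance = 50, seed = 2)
  tpl <- studyTemplates(sc)
  pk1 <- autopickMicrograph(sim$micrograph, tpl, ctf = NULL,
                            threshold = 0.25, diameter = sc$diameter)
  shifted <- micrograph(3.7 * pixels(sim$micrograph) + 120,
                        pixelSize = sc$pixelSize)
  pk2 <- autopickMicrograph(shifted, tpl, ctf = NULL, threshold = 0.25,
                            diameter = sc$diameter)
  p1 <- picks(pk1); p2 <- picks(pk2)
  expect_equal(p1[c("x", "y", "k")], p2[c("x", "y", "k")])
  expect_equal(p1$s, p2$s, tolerance = 1e-5)
  # in-plane angles agree modulo the template's own symmetry (the disc is
  # fully symmetric, the rod two-fold; symmetric rotations tie in S and
  # round-off may break the tie either way)
  rod <- p1$k == 1L
  expect_true(all(angleDiff(p1$phi[rod], p2$phi[rod], 180) < 1e-6))
})

test_that("raising the threshold never increases the number of picks", {
  sc <- studyConditions()
  sim <- simulateMicrograph(shape = c(256, 256), pixelSize = sc$pixelSize,
                            nParticles = 4, templates = sc$raw,
                            boxSize = sc$boxSize,
                            maskRadius = sc$maskRadius, snr = sc$snr,
                            minDistance = 50, seed = 3)
  curve <- benchmarkSuite(thresholds = c(0.05, 0.15, 0.25, 0.5, 0.9),
                          sim = sim, diameter = sc$diameter)
  expect_true(all(diff(curve$nPicks) <= 0))
  expect_true(all(diff(curve$recall) <= 0))
})

test_that("a threshold above the global maximum yields an empty pick set", {
  sc <- studyConditions()
  sim <- simulateMicrograph(shape = c(192, 192), pixelSize = sc$pixelSize,
                            nParticles = 0, templates = sc$raw,
                            boxSize = sc$boxSize,
                            maskRadius = sc$maskRadius, snr = sc$snr,
                            seed = 4)
  pk <- autopickMicrograph(sim$micrograph, studyTemplates(sc), ctf = NULL,
                           threshold = 2, diameter = sc$diameter,
                           angularStep = 45)
  expect_equal(nPicks(pk), 0L)
})

test_that("FOM maps hold the rotation-wise maximum and round-trip to disk", {
  sc <- studyConditions()
  masks <- makeMasks(sc$boxSize, sc$maskRadius)
  sim <- simulateMicrograph(shape = c(192, 192), pixelSize = sc$pixelSize,
                            nParticles = 2, templates = sc$raw,
                            boxSize = sc$boxSize,
                            maskRadius = sc$maskRadius, snr = sc$snr,
                            minDistance = 60, seed = 5)
  X <- pixels(sim$micrograph)
  st <- localBackgroundStats(X, masks)
  bank <- prepareTemplates(studyTemplates(sc), ctf = NULL, masks = masks,
                           cutoff = 20, angles = rotationGrid(90),
                           pixelSize = sc$pixelSize)
  fom <- buildFomMaps(X, bank, st)
  # the FOM dominates every per-rotation map; compare in the log-ratio
  # domain where float32 quantisation is an absolute perturbation
  for (j in seq_along(bank@angles)) {
    e <- similarityMap(X, bank@images[[1L]][[j]], st, masks,
                       logE = bank@logE[1L], what = "exponent")
    ok <- e > -1e29
    expect_true(all(fom@expo[[1L]][ok] >= e[ok] - 1e-3))
  }
  # with a single rotation the FOM equals the similarity map up to the
  # single-precision quantisation applied at construction
  b1 <- prepareTemplates(studyTemplates(sc), ctf = NULL, masks = masks,
                         cutoff = 20, angles = 0,
                         pixelSize = sc$pixelSize)
  fom1 <- buildFomMaps(X, b1, st)
  e1 <- similarityMap(X, b1@images[[1L]][[1L]], st, masks,
                      logE = b1@logE[1L], what = "exponent")
  ok <- e1 > -1e29
  expect_equal(fom1@expo[[1L]][ok], e1[ok], tolerance = 1e-3)
  # disk round trip reproduces picking bit-identically
  dir <- withr::local_tempdir()
  writeFomMaps(fom, dir)
  back <- readFomMaps(dir)
  pkMem <- picksFromFomMaps(fom, threshold = 0.25, minDistance = 18)
  pkDisk <- picksFromFomMaps(back, threshold = 0.25, minDistance = 18)
  expect_identical(picks(pkMem), picks(pkDisk))
  # sidecar/map mismatch is refused
  file.remove(file.path(dir, "fom_k02_expo.mrc"))
  writeMRC(matrix(0, 8, 8), file.path(dir, "fom_k02_expo.mrc"))
  expect_error(readFomMaps(dir), "sidecar")
})

test_that("picking recovers planted particles with correct identity", {
  sc <- studyConditions()
  sim <- simulateMicrograph(shape = c(320, 320), pixelSize = sc$pixelSize,
                            nParticles = 8, templates = sc$raw,
                            boxSize = sc$boxSize,
                            maskRadius = sc$maskRadius, snr = sc$snr,
                            minDistance = 45, seed = 6)
  pk <- autopickMicrograph(sim$micrograph, studyTemplates(sc), ctf = NULL,
                           threshold = 0.25, diameter = sc$diameter)
  ev <- evaluatePicking(pk, sim$truth,
                        matchRadius = 0.25 * sc$diameter / sc$pixelSize)
  m <- evalMetrics(ev)
  expect_gte(m$recall, 0.85)
  expect_lte(m$fp, 1L)
  mt <- evalMatches(ev)
  agree <- sum(picks(pk)$k[mt$pick] == sim$truth$k[mt$truth])
  expect_gte(agree / nrow(mt), 0.85)
})
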
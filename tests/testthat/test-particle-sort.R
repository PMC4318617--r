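test_that("particle extraction normalises and respects the frame margin", {
  sc <- studyConditions()
  masks <- makeMasks(sc$boxSize, sc$maskRadius)
  sim <- simulateMicrograph(shape = c(256, 256), pixelSize = sc$pixelSize,
                            nParticles = 3, templates = sc$raw,
                            boxSize = sc$boxSize,
                            maskRadius = sc$maskRadius, snr = sc$snr,
                            minDistance = 60, seed = 8)
  tr <- sim$truth[1L, ]
  part <- extractParticle(sim$micrograph, tr$x, tr$y, masks)
  bg <- part[outerMask(masks) == 1]
  expect_lt(abs(mean(bg)), 1e-10)
  expect_lt(abs(sqrt(mean((bg - mean(bg))^2)) - 1), 1e-10)
  # the extraction correlates with the planted projection at this SNR
  stamp <- rotateTemplate(sc$raw[[tr$k + 1L]], tr$phi)
  inMi <- innerMask(masks) == 1
  expect_gt(cor(part[inMi], stamp[inMi]), 0.5)
  # margin contract: one pixel inside works, on the boundary fails
  half <- (sc$boxSize - 1) / 2
  expect_silent(extractParticle(sim$micrograph, half, half, masks))
  expect_error(extractParticle(sim$micrograph, half - 1, half, masks),
               "leaves the micrograph")
})

test_that("difference-image features vanish for a perfect match and track noise", {
  m <- makeMasks(32, 11)
  set.seed(13)
  tpl <- discTemplate(32, 8) * innerMask(m)
  f0 <- differenceFeatures(tpl, tpl, m)
  expect_identical(unname(f0), rep(0, 5))
  # pure N(0,1) residual: all features near their Gaussian expectations
  part <- tpl + matrix(rnorm(1024), 32, 32)
  f <- differenceFeatures(part, tpl, m)
  bound <- 5 / sqrt(nInner(m))
  expect_lt(abs(f[["diffMean"]]), bound)
  expect_lt(abs(f[["diffStd"]] - 1), bound)
  expect_lt(abs(f[["diffSkew"]]), 3 * bound)
  expect_lt(abs(f[["diffKurt"]]), 6 * bound)
  expect_lt(f[["quadStdSpread"]], 3 * bound)
  # adding a constant shifts only the mean feature
  f2 <- differenceFeatures(part + 3.25, tpl, m)
  expect_equal(f2[["diffMean"]], f[["diffMean"]] + 3.25, tolerance = 1e-10)
  expect_equal(unname(f2[-1L]), unname(f[-1L]), tolerance = 1e-10)
})

test_that("Z-score ranking is exact, stable and scale-invariant", {
  # identical particles: all scores zero, input order retained
  same <- matrix(rep(c(1, 2, 3, 4, 5), each = 4L), 4L, 5L)
  r0 <- zscoreRank(same)
  expect_true(all(r0$avgZ == 0))
  expect_equal(r0$particle, 1:4)
  # a 10-sigma outlier on every feature ranks first
  set.seed(14)
  feats <- matrix(rnorm(20 * 5), 20, 5)
  means <- colMeans(feats)
  sds <- apply(feats, 2L, function(v) sqrt(mean((v - mean(v))^2)))
  feats <- rbind(feats, means + 10 * sds)
  r <- zscoreRank(feats)
  expect_equal(r$particle[1L], 21L)
  # avg Z equals an independent recomputation
  zref <- sapply(seq_len(ncol(feats)), function(j) {
    v <- feats[, j]
    abs(v - mean(v)) / sqrt(mean((v - mean(v))^2))
  })
  expect_equal(r$avgZ[order(r$particle)], rowMeans(zref),
               tolerance = 1e-10)
  # affine rescaling of one feature column cannot change the ranking
  feats2 <- feats
  feats2[, 3L] <- feats2[, 3L] * 1e4 - 77
  expect_equal(zscoreRank(feats2)$particle, r$particle)
  expect_error(zscoreRank(feats[1L, , drop = FALSE]), "at least 2")
})

test_that("sorting reports round-trip and support top-N discarding", {
  sc <- studyConditions()
  sim <- simulateMicrograph(shape = c(320, 320), pixelSize = sc$pixelSize,
                            nParticles = 6, templates = sc$raw,
                            boxSize = sc$boxSize,
                            maskRadius = sc$maskRadius, snr = sc$snr,
                            minDistance = 48, nArtifacts = 2, seed = 15)
  bank <- prepareTemplates(studyTemplates(sc), ctf = NULL,
                           masks = sim$masks, cutoff = 20,
                           angles = rotationGrid(15),
                           pixelSize = sc$pixelSize)
  cc <- rbind(data.frame(x = sim$truth$x, y = sim$truth$y,
                         k = sim$truth$k,
                         phi = (round(sim$truth$phi / 15) * 15) %% 360,
                         s = 1),
              data.frame(x = sim$artifacts$x, y = sim$artifacts$y,
                         k = 0L, phi = 0, s = 1))
  pk <- pickSet(cc, pixelSize = sc$pixelSize, boxSize = sc$boxSize)
  ranked <- sortParticles(sim$micrograph, pk, bank)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "sorted.star")
  writeSortStar(ranked, f)
  back <- readSortStar(f)
  expect_equal(back$rank, ranked$rank)
  expect_equal(back$avgZ, ranked$avgZ, tolerance = 1e-9)
  expect_equal(back$x, ranked$x)
  # discarding the top N removes exactly N (the worst-ranked) rows
  writeSortStar(ranked, f, discardTop = 3L)
  kept <- readSortStar(f)
  expect_equal(nrow(kept), nrow(ranked) - 3L)
  expect_equal(kept$rank, ranked$rank[-(1:3)])
  # the injected high-contrast artifacts lead the ranking
  artRows <- which(ranked$particle > 6L)
  expect_true(all(artRows <= 4L))
})
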
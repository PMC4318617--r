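## The picking core: probability-ratio similarity maps via FFT
## cross-correlation, figure-of-merit (FOM) maps, peak search and pruning.

#' Pad a micrograph to a square with matched Gaussian noise
#'
#' FFT picking operates on square images; rectangular micrographs are
#' padded (bottom/right) with white Gaussian noise whose mean and standard
#' deviation match the micrograph's global statistics, drawn from a seeded
#' generator for reproducibility.  The original pixels occupy the top-left
#' region unchanged, so pick coordinates need no offset correction.
#'
#' @param x a \linkS4class{Micrograph}.
#' @param seed integer seed for the padding noise (default 0).
#' @return list with \code{micrograph} (square), \code{origDim} the
#'   original (rows, cols), and \code{offset} always c(0, 0).
#' @export
padToSquare <- function(x, seed = 0L) {
  X <- pixels(x)
  d <- dim(X)
  if (d[1L] == d[2L])
    return(list(micrograph = x, origDim = d, offset = c(0L, 0L)))
  side <- max(d)
  m <- mean(X); s <- stats::sd(X)
  out <- withr::with_seed(seed, {
    P <- matrix(stats::rnorm(side * side, mean = m, sd = s), side, side)
    P[seq_len(d[1L]), seq_len(d[2L])] <- X
    P
  })
  list(micrograph = micrograph(out, pixelSize = pixelSize(x),
                               sourcePath = sourcePath(x)),
       origDim = d, offset = c(0L, 0L))
}

#' Expected probability ratio of a prepared template
#'
#' The expected value of the particle-vs-noise probability ratio under the
#' generative noise model:
#' \deqn{E\langle R_k\rangle = \exp\left(\frac{1}{2|Mi|}\sum_{q} A_k^2(q)\right).}
#' Used to rescale the ratio into the similarity
#' \eqn{S = (R-1)/(E\langle R_k\rangle - 1)} with a predictable operating
#' range.  For strong templates the exponent is better kept in the log
#' domain; see \code{logE} in \linkS4class{TemplateBank}.
#'
#' @param template prepared template (square matrix, zero outside Mi).
#' @param masks a \linkS4class{BoxMasks}.
#' @return scalar expected ratio (1.0 for an all-zero template).
#' @export
expectedRatio <- function(template, masks) {
  exp(sum(template^2) / (2 * masks@nInner))
}

#' Similarity map of one prepared template over a micrograph
#'
#' Evaluates, for every candidate box position t (0-based top-left corner),
#' the log probability ratio between "template A is at t" and "only noise
#' is at t":
#' \deqn{\log R(t) = \frac{1}{\sigma(t)}\sum_q X(q+t)A(q)
#'   - \frac{\mu(t)}{\sigma(t)}\sum_q A(q) - \frac{1}{2}\sum_q A^2(q),}
#' with the position-dependent sum computed by a single FFT
#' cross-correlation, and converts it to the similarity
#' \eqn{S(t) = (R(t)-1)/(E\langle R_k\rangle - 1)} (computed as
#' \code{expm1(logR)/expm1(logE)} to avoid overflow).  Useful picking
#' thresholds on S typically lie in (0, 1].  Invalid positions (background
#' sd below the degeneracy floor, or boxes crossing the true micrograph
#' edge) carry the sentinel -1e30.
#'
#' @param x square \linkS4class{Micrograph} (padded) or matrix.
#' @param template prepared template image.
#' @param stats \linkS4class{LocalStatsMaps} for the same padded
#'   micrograph.
#' @param masks a \linkS4class{BoxMasks}.
#' @param origDim true (unpadded) micrograph dims; candidate boxes must lie
#'   fully inside this region.  Defaults to the padded dims.
#' @param logE log expected ratio to use (per-template value from a
#'   \linkS4class{TemplateBank}); computed from \code{template} if omitted.
#' @param fx optional precomputed \code{fft2} of the micrograph pixels.
#' @param what \code{"similarity"} (default) for S, or \code{"exponent"}
#'   for the overflow-safe log-ratio map.
#' @return numeric matrix (padded-micrograph shape) of S or log R values
#'   with sentinels at invalid positions.
#' @export
similarityMap <- function(x, template, stats, masks, origDim = NULL,
                          logE = NULL, fx = NULL,
                          what = c("similarity", "exponent")) {
  what <- match.arg(what)
  X <- if (is(x, "Micrograph")) pixels(x) else x
  stopIfNot2dSquare(X, "micrograph (pad to square first)")
  sA <- sum(template)
  sA2 <- sum(template^2)
  if (is.null(logE)) logE <- sA2 / (2 * masks@nInner)
  if (expm1(logE) <= 0)
    stop("template has no signal (E<Rk> = 1)", call. = FALSE)
  if (is.null(origDim)) origDim <- dim(X)
  cc <- crossCorrelate(X, template, fx = fx)
  expo <- cc / stats@sigma - (stats@mu / stats@sigma) * sA - 0.5 * sA2
  b <- masks@boxSize
  bad <- !stats@valid
  bad[row(bad) > origDim[1L] - b + 1L] <- TRUE
  bad[col(bad) > origDim[2L] - b + 1L] <- TRUE
  expo[bad] <- fomSentinel()
  if (what == "exponent") return(expo)
  s <- expm1(expo) / expm1(logE)
  s[bad] <- fomSentinel()
  s
}

#' Find thresholded 4-neighbour local maxima
#'
#' Returns the positions whose value strictly exceeds each of the four
#' edge-neighbours and the threshold.  Border rows/columns (where a
#' neighbour is missing) and sentinel-marked positions are never peaks.
#'
#' @param map numeric matrix (similarity or FOM map).
#' @param threshold peaks must exceed this value (strict \code{>}).
#' @return data.frame with 1-based matrix indices \code{row}, \code{col}
#'   and \code{value}, ordered by row then column.
#' @export
findLocalMaxima <- function(map, threshold) {
  nr <- nrow(map); nc <- ncol(map)
  if (nr < 3L || nc < 3L)
    return(data.frame(row = integer(0), col = integer(0),
                      value = numeric(0)))
  ctr <- map[2:(nr - 1L), 2:(nc - 1L), drop = FALSE]
  up <- map[1:(nr - 2L), 2:(nc - 1L), drop = FALSE]
  dn <- map[3:nr, 2:(nc - 1L), drop = FALSE]
  lf <- map[2:(nr - 1L), 1:(nc - 2L), drop = FALSE]
  rt <- map[2:(nr - 1L), 3:nc, drop = FALSE]
  is_peak <- ctr > up & ctr > dn & ctr > lf & ctr > rt &
    ctr > threshold & ctr > fomSentinelGuard()
  idx <- which(is_peak, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(row = integer(0), col = integer(0),
                      value = numeric(0)))
  out <- data.frame(row = idx[, 1L] + 1L, col = idx[, 2L] + 1L,
                    value = ctr[idx])
  out[order(out$row, out$col), , drop = FALSE]
}

#' Prune peaks by a minimum inter-particle distance
#'
#' Greedy recursive pruning: peaks are first clustered by the transitive
#' closure of the "closer than \code{minDistance}" relation; within each
#' cluster the highest remaining peak is kept and every remaining peak
#' closer than \code{minDistance} to it discarded, recursively until the
#' cluster is exhausted.  More than one peak per cluster may therefore
#' survive, but all surviving peaks are pairwise at least
#' \code{minDistance} apart and the global maximum always survives.
#' Equal-valued peaks are ordered by (row, then column) ascending for
#' determinism.
#'
#' @param peaks data.frame with columns \code{row}, \code{col},
#'   \code{value} (as from [findLocalMaxima()]); extra columns are carried
#'   through.
#' @param minDistance minimum allowed pairwise distance in pixels.
#' @return pruned data.frame (subset of the input rows).
#' @export
prunePeaks <- function(peaks, minDistance) {
  n <- nrow(peaks)
  if (n <= 1L || minDistance <= 0) return(peaks)
  d2 <- as.matrix(stats::dist(cbind(peaks$row, peaks$col)))
  close <- d2 < minDistance
  # connected components of the "too close" relation (union-find)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) for (j in which(close[i, ] & seq_len(n) > i)) {
    ri <- findRoot(i); rj <- findRoot(j)
    if (ri != rj) parent[rj] <- ri
  }
  comp <- vapply(seq_len(n), findRoot, integer(1L))
  keep <- logical(n)
  for (cl in unique(comp)) {
    members <- which(comp == cl)
    ord <- members[order(-peaks$value[members], peaks$row[members],
                         peaks$col[members])]
    while (length(ord)) {
      top <- ord[1L]
      keep[top] <- TRUE
      ord <- ord[!close[top, ord]]
    }
  }
  peaks[keep, , drop = FALSE]
}

#' Build figure-of-merit maps for one micrograph
#'
#' For each template k, reduces the per-rotation log probability ratio
#' maps to their pointwise maximum over all sampled rotations, retaining
#' the winning rotation.  Because \eqn{S = (e^{\log R}-1)/(E\langle
#' R_k\rangle-1)} is a fixed increasing transform within one template,
#' this maximum is exactly the maximum of S.  Values are quantised to
#' single precision at construction so that FOM maps written to MRC and
#' read back reproduce peak picking bit-identically.
#'
#' @param x square (padded) \linkS4class{Micrograph}.
#' @param bank a \linkS4class{TemplateBank}.
#' @param stats \linkS4class{LocalStatsMaps} for the same micrograph.
#' @param origDim true (unpadded) micrograph dims (rows, cols).
#' @param micrographName recorded in the map parameters.
#' @param seed padding-noise seed recorded for provenance.
#' @return a \linkS4class{FomMaps}.
#' @export
buildFomMaps <- function(x, bank, stats, origDim = NULL,
                         micrographName = NULL, seed = 0L) {
  X <- if (is(x, "Micrograph")) pixels(x) else x
  if (is.null(origDim)) origDim <- dim(X)
  if (is.null(micrographName))
    micrographName <- if (is(x, "Micrograph")) sourcePath(x) else "<memory>"
  fx <- fft2(X)
  K <- length(bank@images)
  angles <- bank@angles
  expoMaps <- vector("list", K)
  phiMaps <- vector("list", K)
  for (k in seq_len(K)) {
    best <- NULL; bestPhi <- NULL
    for (j in seq_along(angles)) {
      e <- similarityMap(X, bank@images[[k]][[j]], stats, bank@masks,
                         origDim = origDim, logE = bank@logE[k], fx = fx,
                         what = "exponent")
      if (is.null(best)) {
        best <- e
        bestPhi <- matrix(angles[j], nrow(e), ncol(e))
      } else {
        better <- e > best
        best[better] <- e[better]
        bestPhi[better] <- angles[j]
      }
    }
    expoMaps[[k]] <- quantiseFloat32(best)
    phiMaps[[k]] <- bestPhi
  }
  new("FomMaps", expo = expoMaps, phi = phiMaps, logE = bank@logE,
      params = list(origDim = as.integer(origDim),
                    paddedSide = nrow(X),
                    boxSize = bank@boxSize,
                    radius = bank@masks@radius,
                    angularStep = if (length(angles) > 1L)
                      angles[2L] - angles[1L] else 360,
                    nTemplates = K,
                    pixelSize = bank@pixelSize,
                    lowpassCutoff = bank@lowpassCutoff,
                    micrographName = micrographName,
                    seed = as.integer(seed)))
}

#' Pick particles from figure-of-merit maps
#'
#' Threshold-and-prune peak selection on prepared FOM maps: per template,
#' 4-neighbour local maxima of the best-over-rotations map exceeding the
#' similarity threshold are pruned by the minimum inter-particle distance;
#' the per-template survivors are then combined and pruned once more, so
#' the final picks are pairwise separated regardless of template.  Because
#' only thresholding and pruning remain, re-picking at a new threshold or
#' distance takes seconds.
#'
#' @param fom a \linkS4class{FomMaps}.
#' @param threshold similarity threshold on S (strict \code{>}; 0.3 by
#'   convention).
#' @param minDistance minimum inter-particle distance in pixels.
#' @return a \linkS4class{PickSet} with particle-centre coordinates in the
#'   unpadded micrograph frame.
#' @export
picksFromFomMaps <- function(fom, threshold = 0.3, minDistance) {
  K <- length(fom@expo)
  b <- fom@params$boxSize
  half <- (b - 1) / 2
  perK <- vector("list", K)
  for (k in seq_len(K)) {
    em1 <- expm1(fom@logE[k])
    # threshold on S translated into the log-ratio domain
    arg <- 1 + threshold * em1
    eThr <- if (arg <= 0) -Inf else log(arg)
    pk <- findLocalMaxima(fom@expo[[k]], eThr)
    pk <- prunePeaks(pk, minDistance)
    if (nrow(pk)) {
      pk$k <- k - 1L
      pk$phi <- fom@phi[[k]][cbind(pk$row, pk$col)]
      pk$s <- expm1(pk$value) / em1
    } else {
      pk$k <- integer(0); pk$phi <- numeric(0); pk$s <- numeric(0)
    }
    perK[[k]] <- pk
  }
  comb <- do.call(rbind, perK)
  if (nrow(comb)) {
    # combined pruning compares similarities across templates
    comb$value <- comb$s
    comb <- comb[order(comb$row, comb$col), , drop = FALSE]
    comb <- prunePeaks(comb, minDistance)
  }
  coords <- data.frame(x = (comb$col - 1L) + half,
                       y = (comb$row - 1L) + half,
                       k = as.integer(comb$k),
                       phi = comb$phi,
                       s = comb$s)
  coords <- coords[order(-coords$s, coords$y, coords$x), , drop = FALSE]
  pickSet(coords, micrographName = fom@params$micrographName,
          pixelSize = fom@params$pixelSize, boxSize = b)
}

#' Write figure-of-merit maps to disk
#'
#' One MRC per template holding the best log-ratio map and one holding the
#' winning rotation (degrees), plus a STAR sidecar recording the picking
#' geometry; [readFomMaps()] checks the sidecar and reproduces picking
#' bit-identically.
#'
#' @param fom a \linkS4class{FomMaps}.
#' @param dir output directory (created if needed).
#' @param basename file-name stem.
#' @return the sidecar path, invisibly.
#' @export
writeFomMaps <- function(fom, dir, basename = "fom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- length(fom@expo)
  ps <- fom@params$pixelSize
  for (k in seq_len(K)) {
    writeMRC(fom@expo[[k]],
             file.path(dir, sprintf("%s_k%02d_expo.mrc", basename, k)),
             pixelSize = ps)
    writeMRC(fom@phi[[k]],
             file.path(dir, sprintf("%s_k%02d_phi.mrc", basename, k)),
             pixelSize = ps)
  }
  sidecar <- file.path(dir, paste0(basename, ".star"))
  p <- fom@params
  writeStarFile(list(fomParams = list(fields = list(
    cpOrigRows = p$origDim[1L], cpOrigCols = p$origDim[2L],
    cpPaddedSide = p$paddedSide, cpBoxSize = p$boxSize,
    cpRadius = p$radius, cpAngularStep = p$angularStep,
    cpNTemplates = p$nTemplates, cpPixelSize = p$pixelSize,
    cpLowpassCutoff = p$lowpassCutoff,
    cpMicrographName = p$micrographName, cpSeed = p$seed),
    table = data.frame(cpTemplateIndex = seq_len(K) - 1L,
                       cpLogExpectedRatio = fom@logE))), sidecar)
  invisible(sidecar)
}

#' Read figure-of-merit maps from disk
#'
#' @param dir directory written by [writeFomMaps()].
#' @param basename file-name stem.
#' @return a \linkS4class{FomMaps}.
#' @export
readFomMaps <- function(dir, basename = "fom") {
  sidecar <- file.path(dir, paste0(basename, ".star"))
  blocks <- readStarFile(sidecar)
  blk <- blocks$fomParams
  if (is.null(blk))
    stop("FOM sidecar ", sidecar, " lacks the fomParams block",
         call. = FALSE)
  f <- blk$fields
  K <- as.integer(f$cpNTemplates)
  logE <- as.numeric(blk$table$cpLogExpectedRatio)
  if (length(logE) != K)
    stop("FOM sidecar ", sidecar, " parameter mismatch: ", K,
         " templates declared but ", length(logE), " logE rows",
         call. = FALSE)
  expoMaps <- vector("list", K)
  phiMaps <- vector("list", K)
  for (k in seq_len(K)) {
    e <- readMRC(file.path(dir, sprintf("%s_k%02d_expo.mrc", basename, k)))
    p <- readMRC(file.path(dir, sprintf("%s_k%02d_phi.mrc", basename, k)))
    if (e$nz != 1L || p$nz != 1L ||
        nrow(e$data) != f$cpPaddedSide || ncol(e$data) != f$cpPaddedSide)
      stop("FOM map files under ", dir,
           " do not match the sidecar geometry", call. = FALSE)
    expoMaps[[k]] <- e$data
    phiMaps[[k]] <- p$data
  }
  new("FomMaps", expo = expoMaps, phi = phiMaps, logE = logE,
      params = list(origDim = as.integer(c(f$cpOrigRows, f$cpOrigCols)),
                    paddedSide = as.integer(f$cpPaddedSide),
                    boxSize = as.integer(f$cpBoxSize),
                    radius = as.numeric(f$cpRadius),
                    angularStep = as.numeric(f$cpAngularStep),
                    nTemplates = K,
                    pixelSize = as.numeric(f$cpPixelSize),
                    lowpassCutoff = as.numeric(f$cpLowpassCutoff),
                    micrographName = as.character(f$cpMicrographName),
                    seed = as.integer(f$cpSeed)))
}

#' Automated particle picking on one micrograph
#'
#' The full CTF-corrected template-matching pipeline: pad the micrograph to
#' a square with matched noise; precompute the local background mean/sd
#' fields by FFT; prepare the rotated, CTF-modulated, low-pass filtered
#' template bank; evaluate the probability-ratio similarity for every
#' template, rotation and position; reduce to per-template FOM maps; and
#' select thresholded local maxima pruned by the minimum inter-particle
#' distance (per template, then once more after combining templates).
#'
#' @param x a \linkS4class{Micrograph}.
#' @param templates a \linkS4class{TemplateSet} (pixel size must match the
#'   micrograph).
#' @param ctf a \linkS4class{CtfParams} for this micrograph, or NULL to
#'   pick without CTF modulation.
#' @param threshold similarity threshold (default 0.3).
#' @param diameter particle diameter in Angstrom; the mask radius R is
#'   half of it.
#' @param minDistance minimum inter-particle distance in Angstrom;
#'   defaults to two-thirds of \code{diameter} (useful values are 60-90\%
#'   of the particle diameter).
#' @param angularStep in-plane angular sampling in degrees (default 5,
#'   i.e. 72 rotations).
#' @param lowpassCutoff template low-pass cutoff in Angstrom (default 20).
#' @param invertContrast set TRUE when particles are dark in the
#'   micrograph (raw cryo-EM convention) and templates are white.
#' @param seed seed for the padding noise (default 0).
#' @param fomDir optional directory: when given, FOM maps are written
#'   there (or, with \code{readFom = TRUE}, read from there instead of
#'   being recomputed).
#' @param basename file-name stem for FOM maps.
#' @param readFom read previously written FOM maps from \code{fomDir}.
#' @return a \linkS4class{PickSet}.
#' @examples
#' sim <- simulateMicrograph(shape = c(192, 192), nParticles = 4,
#'                           boxSize = 32, maskRadius = 10, snr = 2,
#'                           minDistance = 40, seed = 7)
#' ts <- templateSet(list(discTemplate(32, 8), rodTemplate(32, 20, 8)),
#'                   pixelSize = 1)
#' pk <- autopickMicrograph(sim$micrograph, ts, ctf = NULL,
#'                          threshold = 0.25, diameter = 20)
#' nPicks(pk)
#' @export
autopickMicrograph <- function(x, templates, ctf = NULL, threshold = 0.3,
                               diameter, minDistance = NULL,
                               angularStep = 5, lowpassCutoff = 20,
                               invertContrast = FALSE, seed = 0L,
                               fomDir = NULL, basename = "fom",
                               readFom = FALSE) {
  ps <- pixelSize(x)
  if (abs(ps - pixelSize(templates)) > 1e-6 * ps)
    stop("micrograph (", ps, " A/px) and templates (",
         pixelSize(templates), " A/px) disagree on pixel size",
         call. = FALSE)
  if (is.null(minDistance)) minDistance <- (2 / 3) * diameter
  minDistPx <- minDistance / ps
  if (readFom) {
    if (is.null(fomDir)) stop("readFom = TRUE requires fomDir",
                              call. = FALSE)
    fom <- readFomMaps(fomDir, basename)
  } else {
    if (invertContrast)
      x <- micrograph(-pixels(x), pixelSize = ps,
                      sourcePath = sourcePath(x))
    radius <- diameter / (2 * ps)
    masks <- makeMasks(boxSize(templates), radius)
    padded <- padToSquare(x, seed = seed)
    stats <- localBackgroundStats(padded$micrograph, masks)
    bank <- prepareTemplates(templates, ctf = ctf, masks = masks,
                             cutoff = lowpassCutoff,
                             angles = rotationGrid(angularStep),
                             pixelSize = ps)
    fom <- buildFomMaps(padded$micrograph, bank, stats,
                        origDim = padded$origDim,
                        micrographName = sourcePath(x), seed = seed)
    if (!is.null(fomDir)) writeFomMaps(fom, fomDir, basename)
  }
  picksFromFomMaps(fom, threshold = threshold, minDistance = minDistPx)
}
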
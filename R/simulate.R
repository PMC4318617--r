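## Synthetic micrographs with known ground truth, emulating the generative
## model the picker assumes: spatially varying additive/multiplicative
## noise fields plus rotated, optionally CTF-convolved template stamps.

#' Analytic disc template (top-view-like)
#'
#' A soft-edged disc of unit plateau amplitude, centred at
#' \code{((box-1)/2, (box-1)/2)}, with a raised-cosine edge.
#'
#' @param boxSize box side in pixels.
#' @param radius disc radius in pixels.
#' @param edgeWidth soft-edge width in pixels.
#' @return square numeric matrix.
#' @export
discTemplate <- function(boxSize, radius, edgeWidth = 2) {
  ctr <- (boxSize - 1) / 2
  d <- (seq_len(boxSize) - 1) - ctr
  r <- sqrt(outer(d^2, d^2, "+"))
  softEdge(r, radius, edgeWidth)
}

#' Analytic rounded-rod template (side-view-like)
#'
#' A rectangle with rounded ends (capsule) of unit plateau amplitude,
#' axis along x, centred in the box; with the disc template this gives a
#' two-template set exercising multi-template picking and in-plane angle
#' recovery (the rod breaks rotational symmetry modulo 180 degrees).
#'
#' @param boxSize box side in pixels.
#' @param length total capsule length in pixels (along x).
#' @param width capsule width in pixels.
#' @param edgeWidth soft-edge width in pixels.
#' @return square numeric matrix.
#' @export
rodTemplate <- function(boxSize, length, width, edgeWidth = 2) {
  ctr <- (boxSize - 1) / 2
  halfCore <- max(0, length / 2 - width / 2)
  d <- (seq_len(boxSize) - 1) - ctr
  dx <- matrix(d, boxSize, boxSize, byrow = TRUE)
  dy <- matrix(d, boxSize, boxSize)
  # distance to the core segment y = 0, |x| <= halfCore
  ax <- pmax(abs(dx) - halfCore, 0)
  r <- sqrt(ax^2 + dy^2)
  softEdge(r, width / 2, edgeWidth)
}

softEdge <- function(r, radius, edgeWidth) {
  out <- matrix(0, nrow(r), ncol(r))
  out[r <= radius - edgeWidth] <- 1
  band <- r > radius - edgeWidth & r < radius
  out[band] <- 0.5 * (1 + cos(pi * (r[band] - (radius - edgeWidth)) /
                                edgeWidth))
  out
}

buildField <- function(spec, nr, nc) {
  if (is.numeric(spec) && length(spec) == 1L)
    spec <- list(kind = "constant", value = spec)
  kind <- spec$kind
  if (kind == "constant") return(matrix(spec$value, nr, nc))
  if (kind == "gradient") {
    dir <- if (is.null(spec$direction)) "x" else spec$direction
    u <- switch(dir,
      x = matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE),
      y = matrix(seq(0, 1, length.out = nr), nr, nc),
      diag = (matrix(seq(0, 1, length.out = nr), nr, nc) +
                matrix(seq(0, 1, length.out = nc), nr, nc,
                       byrow = TRUE)) / 2,
      stop("unknown gradient direction: ", dir, call. = FALSE))
    return(spec$low + (spec$high - spec$low) * u)
  }
  stop("unknown field kind: ", kind, call. = FALSE)
}

#' Simulate a micrograph with known ground truth
#'
#' Draws a micrograph from the generative model the picker assumes:
#' \deqn{X = \mu_{field} + \sigma_{field} \cdot N(0,1) + \sum_i c_i
#'   A_{k_i\phi_i}(r - t_i),}
#' i.e. spatially varying additive and multiplicative noise fields
#' (emulating ice-thickness and dose variation) plus rotated, optionally
#' CTF-convolved template stamps at rejection-sampled positions.  Each
#' stamp is scaled so that the mean squared signal within the particle
#' mask Mi equals \code{snr} times the local noise variance.  Optional
#' high-variance artifact blobs emulate ice/junk false positives for the
#' sorting benchmark.  Fully deterministic given \code{seed}.
#'
#' @param shape micrograph (rows, cols) in pixels.
#' @param pixelSize Angstrom per pixel.
#' @param nParticles number of planted particles N.
#' @param templates list of square template matrices (default: the disc
#'   and rod analytic pair at the given box size).
#' @param boxSize template box side in pixels (used for the defaults and
#'   the placement margin).
#' @param maskRadius particle-mask radius R in pixels (defines the Mi over
#'   which the SNR is measured).
#' @param snr ratio of mean squared in-Mi signal to local noise variance.
#' @param muField,sigmaField field specs: a single number (constant) or
#'   \code{list(kind = "gradient", low =, high =, direction = "x"|"y"|"diag")}.
#' @param ctf optional \linkS4class{CtfParams}; when given, each stamp is
#'   CTF-convolved before planting.
#' @param minDistance minimum pairwise centre distance between planted
#'   records in pixels (default two-thirds of the mask diameter).
#' @param nArtifacts number of high-variance junk blobs to add.
#' @param seed integer seed.
#' @return list with \code{micrograph} (a \linkS4class{Micrograph}),
#'   \code{truth} (data.frame x, y, k, phi: 0-based centre coordinates,
#'   0-based template index, degrees), \code{artifacts} (data.frame x, y)
#'   and \code{masks} (the \linkS4class{BoxMasks} used for scaling).
#' @export
simulateMicrograph <- function(shape = c(512, 512), pixelSize = 1,
                               nParticles = 20, templates = NULL,
                               boxSize = 48, maskRadius = 12, snr = 2,
                               muField = 0, sigmaField = 1, ctf = NULL,
                               minDistance = NULL, nArtifacts = 0,
                               seed = 1L) {
  nr <- shape[1L]; nc <- shape[2L]
  if (is.null(templates))
    templates <- list(discTemplate(boxSize, 0.7 * maskRadius),
                      rodTemplate(boxSize, 1.8 * maskRadius,
                                  0.7 * maskRadius))
  b <- nrow(templates[[1L]])
  masks <- makeMasks(b, maskRadius)
  if (is.null(minDistance)) minDistance <- (4 / 3) * maskRadius
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  nPlace <- nParticles + nArtifacts
  if (nPlace * minDistance^2 > 0.5 * nr * nc)
    stop("placement infeasible: too many particles for the image area; ",
         "request fewer particles", call. = FALSE)
  withr::with_seed(seed, {
    muF <- buildField(muField, nr, nc)
    sigF <- buildField(sigmaField, nr, nc)
    if (any(sigF <= 0)) stop("sigma field must be positive everywhere",
                             call. = FALSE)
    X <- muF + sigF * matrix(stats::rnorm(nr * nc), nr, nc)
    # rejection-sampled corner positions, pairwise centre separation
    corners <- matrix(0, 0L, 2L)  # 0-based (row, col)
    tries <- 0L
    maxTries <- 1000L * max(1L, nPlace)
    while (nrow(corners) < nPlace) {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("could not place ", nPlace, " particles at min distance ",
             minDistance, " after ", maxTries,
             " tries; request fewer particles", call. = FALSE)
      cand <- c(sample.int(nr - b + 1L, 1L) - 1L,
                sample.int(nc - b + 1L, 1L) - 1L)
      if (nrow(corners) == 0L ||
          all(sqrt(rowSums(sweep(corners, 2L, cand)^2)) >= minDistance))
        corners <- rbind(corners, cand)
    }
    half <- (b - 1) / 2
    truth <- data.frame(x = numeric(0), y = numeric(0), k = integer(0),
                        phi = numeric(0))
    for (i in seq_len(nParticles)) {
      k <- sample.int(length(templates), 1L)
      phi <- stats::runif(1L, 0, 360)
      stamp <- rotateTemplate(templates[[k]], phi)
      if (!is.null(ctf))
        stamp <- applyCtfToTemplate(stamp, ctf, pixelSize)
      r0 <- corners[i, 1L]; c0 <- corners[i, 2L]
      sigLoc <- sigF[round(r0 + half) + 1L, round(c0 + half) + 1L]
      meanA2 <- sum((stamp * masks@mi)^2) / masks@nInner
      if (meanA2 <= 0) stop("degenerate template stamp", call. = FALSE)
      scale <- sigLoc * sqrt(snr / meanA2)
      rows <- (r0 + 1L):(r0 + b); cols <- (c0 + 1L):(c0 + b)
      X[rows, cols] <- X[rows, cols] + scale * stamp
      truth <- rbind(truth, data.frame(x = c0 + half, y = r0 + half,
                                       k = k - 1L, phi = phi))
    }
    artifacts <- data.frame(x = numeric(0), y = numeric(0))
    if (nArtifacts > 0L) {
      blobMask <- discTemplate(b, 0.6 * maskRadius, edgeWidth = 1.5)
      for (i in seq_len(nArtifacts)) {
        r0 <- corners[nParticles + i, 1L]
        c0 <- corners[nParticles + i, 2L]
        sigLoc <- sigF[round(r0 + half) + 1L, round(c0 + half) + 1L]
        amp <- sigLoc * (6 + 2 * stats::runif(1L)) *
          sample(c(-1, 1), 1L)
        texture <- matrix(stats::rnorm(b * b, sd = 2 * sigLoc), b, b)
        rows <- (r0 + 1L):(r0 + b); cols <- (c0 + 1L):(c0 + b)
        X[rows, cols] <- X[rows, cols] + blobMask * (amp + texture)
        artifacts <- rbind(artifacts,
                           data.frame(x = c0 + half, y = r0 + half))
      }
    }
    list(micrograph = micrograph(X, pixelSize = pixelSize,
                                 sourcePath = sprintf("synthetic_seed%d",
                                                      seed)),
         truth = truth, artifacts = artifacts, masks = masks)
  })
}

#' Write simulation ground truth to a STAR file
#'
#' @param truth data.frame (x, y, k, phi) from [simulateMicrograph()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTruthStar <- function(truth, path) {
  tb <- data.frame(truth$x, truth$y, truth$k, truth$phi)
  names(tb) <- unname(PICK_COLUMNS[c("x", "y", "k", "phi")])
  writeStarFile(list(groundTruth = list(table = tb)), path)
}

#' Read simulation ground truth
#'
#' @param path STAR file written by [writeTruthStar()].
#' @return data.frame with columns x, y, k, phi.
#' @export
readTruthStar <- function(path) {
  blocks <- readStarFile(path)
  blk <- NULL
  for (b in blocks) if (!is.null(b$table)) { blk <- b; break }
  if (is.null(blk))
    stop("STAR file ", path, " contains no ground-truth loop",
         call. = FALSE)
  tb <- blk$table
  cols <- PICK_COLUMNS[c("x", "y", "k", "phi")]
  requireStarColumns(tb, unname(cols), path)
  data.frame(x = as.numeric(tb[[cols[["x"]]]]),
             y = as.numeric(tb[[cols[["y"]]]]),
             k = as.integer(tb[[cols[["k"]]]]),
             phi = as.numeric(tb[[cols[["phi"]]]]))
}
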
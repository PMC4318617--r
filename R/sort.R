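## Particle sorting: difference-image statistics and average Z-scores to
## surface high-contrast false positives (ice, aggregates, carbon edges).

#' Extract and normalise one particle image
#'
#' Cuts a box centred on the pick (0-based centre coordinates; the box
#' corner is rounded to the nearest pixel) and applies the background
#' normalisation of [normalizeParticle()].
#'
#' @param x a \linkS4class{Micrograph}.
#' @param xCoord,yCoord 0-based particle-centre coordinates (x = column,
#'   y = row).
#' @param masks a \linkS4class{BoxMasks} defining box size and Mi/Mo.
#' @return normalised particle image (square matrix).
#' @export
extractParticle <- function(x, xCoord, yCoord, masks) {
  X <- pixels(x)
  b <- masks@boxSize
  half <- (b - 1) / 2
  c0 <- round(xCoord - half)   # 0-based corner column
  r0 <- round(yCoord - half)   # 0-based corner row
  if (r0 < 0 || c0 < 0 || r0 + b > nrow(X) || c0 + b > ncol(X))
    stop("particle box at (", xCoord, ", ", yCoord,
         ") leaves the micrograph frame", call. = FALSE)
  sub <- X[(r0 + 1L):(r0 + b), (c0 + 1L):(c0 + b)]
  normalizeParticle(sub, masks)
}

#' Difference-image features of one particle
#'
#' Subtracts the particle's aligned template and summarises the residual
#' within the particle mask Mi by five statistics: mean, (population)
#' standard deviation, skewness, excess kurtosis, and the standard
#' deviation between the standard deviations of the four box quadrants
#' (each intersected with Mi).  For a correctly picked particle the
#' residual is background noise and all five are near their Gaussian
#' expectations; junk leaves structured residuals.  Skewness and kurtosis
#' are defined as 0 when the residual standard deviation is 0.
#'
#' @param particle normalised particle image (see [extractParticle()]).
#' @param template the prepared template in the particle's recorded
#'   in-plane orientation.
#' @param masks a \linkS4class{BoxMasks}.
#' @return named numeric vector: \code{diffMean}, \code{diffStd},
#'   \code{diffSkew}, \code{diffKurt}, \code{quadStdSpread}.
#' @export
differenceFeatures <- function(particle, template, masks) {
  if (!identical(dim(particle), dim(template)))
    stop("particle and template shapes differ", call. = FALSE)
  D <- particle - template
  inMi <- masks@mi == 1
  v <- D[inMi]
  m <- mean(v)
  s <- popSd(v)
  if (s > 0) {
    z <- (v - m) / s
    skew <- mean(z^3)
    kurt <- mean(z^4) - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  b <- masks@boxSize
  hb <- floor(b / 2)
  rowHalf <- row(D) <= hb
  colHalf <- col(D) <= hb
  quadStd <- vapply(list(rowHalf & colHalf, rowHalf & !colHalf,
                         !rowHalf & colHalf, !rowHalf & !colHalf),
                    function(q) {
                      w <- D[q & inMi]
                      if (length(w) < 2L) 0 else popSd(w)
                    }, numeric(1L))
  c(diffMean = m, diffStd = s, diffSkew = skew, diffKurt = kurt,
    quadStdSpread = popSd(quadStd))
}

#' Rank particles by average absolute Z-score
#'
#' For each feature column, Z-scores are computed as the absolute
#' deviation from the feature's mean over all particles in units of the
#' feature's (population) standard deviation (0 when that deviation is
#' 0), so deviation in either direction counts as suspicious.  Particles
#' are ranked by the average of their Z-scores, worst (highest) first;
#' ties keep input order.
#'
#' @param features numeric matrix or data.frame, one row per particle,
#'   one column per feature (needs at least 2 particles).
#' @return data.frame with the input features, per-feature Z-score columns
#'   (prefix \code{z}), \code{avgZ}, \code{particle} (input row index) and
#'   \code{rank}; rows ordered by decreasing \code{avgZ}.
#' @export
zscoreRank <- function(features) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (n < 2L)
    stop("Z-score ranking needs at least 2 particles", call. = FALSE)
  zs <- lapply(features, function(col) {
    m <- mean(col); s <- popSd(col)
    if (s > 0) abs(col - m) / s else rep(0, n)
  })
  names(zs) <- paste0("z", toupper(substring(names(features), 1L, 1L)),
                      substring(names(features), 2L))
  out <- cbind(features, as.data.frame(zs))
  out$avgZ <- rowMeans(as.data.frame(zs))
  out$particle <- seq_len(n)
  out <- out[order(-out$avgZ), , drop = FALSE]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  out
}

#' Sort picked particles by difference-image Z-scores
#'
#' Runs the full sorting algorithm for one micrograph: every pick is
#' extracted and normalised, its prepared template (the template index and
#' in-plane rotation recorded at picking time) subtracted, the five
#' difference-image features computed within Mi, and all particles ranked
#' by average absolute Z-score.  Sorting may be re-run at any later stage
#' by supplying a different template assignment (e.g. after
#' classification) through the pick table.
#'
#' @param x a \linkS4class{Micrograph}.
#' @param pickSet a \linkS4class{PickSet} for that micrograph.
#' @param bank the \linkS4class{TemplateBank} used for picking (or an
#'   equivalently prepared one).
#' @return data.frame as from [zscoreRank()], plus the pick coordinates;
#'   ordered worst-first.
#' @export
sortParticles <- function(x, pickSet, bank) {
  cc <- picks(pickSet)
  if (nrow(cc) < 2L)
    stop("sorting needs at least 2 picked particles", call. = FALSE)
  feats <- matrix(0, nrow(cc), 5L)
  for (i in seq_len(nrow(cc))) {
    part <- extractParticle(x, cc$x[i], cc$y[i], bank@masks)
    jPhi <- which.min(abs(bank@angles - cc$phi[i] %% 360))
    tmpl <- bank@images[[cc$k[i] + 1L]][[jPhi]]
    feats[i, ] <- differenceFeatures(part, tmpl, bank@masks)
  }
  colnames(feats) <- c("diffMean", "diffStd", "diffSkew", "diffKurt",
                       "quadStdSpread")
  ranked <- zscoreRank(feats)
  idx <- ranked$particle
  ranked$x <- cc$x[idx]; ranked$y <- cc$y[idx]
  ranked$k <- cc$k[idx]; ranked$phi <- cc$phi[idx]; ranked$s <- cc$s[idx]
  ranked
}

SORT_COLUMNS <- c(x = "rlnCoordinateX", y = "rlnCoordinateY",
                  k = "rlnClassNumber", phi = "rlnAnglePsi",
                  s = "rlnAutopickFigureOfMerit",
                  diffMean = "cpDiffMean", diffStd = "cpDiffStd",
                  diffSkew = "cpDiffSkew", diffKurt = "cpDiffKurt",
                  quadStdSpread = "cpQuadStdSpread", avgZ = "cpAverageZscore",
                  rank = "cpSortRank")

#' Write a sorting report to a STAR file
#'
#' One row per particle in ranking order (worst first) with coordinates,
#' template assignment, similarity, the five difference-image features,
#' the average Z-score and the rank.  \code{discardTop} drops the N
#' worst-ranked rows before writing (the manual-inspection shortcut:
#' the highest average Z-scores are usually junk).
#'
#' @param ranked data.frame from [sortParticles()].
#' @param path output file path.
#' @param discardTop number of worst-ranked particles to drop (default 0).
#' @return \code{path}, invisibly.
#' @export
writeSortStar <- function(ranked, path, discardTop = 0L) {
  if (discardTop > 0L)
    ranked <- ranked[-seq_len(min(discardTop, nrow(ranked))), ,
                     drop = FALSE]
  tb <- ranked[, names(SORT_COLUMNS)]
  names(tb) <- unname(SORT_COLUMNS)
  writeStarFile(list(sortedPicks = list(table = tb)), path)
}

#' Read a sorting report
#'
#' @param path STAR file written by [writeSortStar()].
#' @return data.frame with internal column names, in file (ranking) order.
#' @export
readSortStar <- function(path) {
  blocks <- readStarFile(path)
  blk <- NULL
  for (b in blocks) if (!is.null(b$table)) { blk <- b; break }
  if (is.null(blk))
    stop("STAR file ", path, " contains no sorting loop", call. = FALSE)
  tb <- blk$table
  requireStarColumns(tb, unname(SORT_COLUMNS), path)
  out <- tb[, unname(SORT_COLUMNS)]
  names(out) <- names(SORT_COLUMNS)
  out
}
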
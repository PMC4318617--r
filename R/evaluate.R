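## Scoring picking output against reference coordinates.

#' Evaluate picks against ground truth
#'
#' One-to-one greedy matching: all (pick, truth) pairs within
#' \code{matchRadius} are sorted by distance ascending and accepted when
#' both ends are still unmatched.  TP is the number of accepted pairs, FP
#' the unmatched picks, FN the unmatched truths; recall = TP/(TP+FN),
#' precision = TP/(TP+FP), FDR = FP/(TP+FP) = 1 - precision.  With no
#' picks at all, precision and FDR are undefined and reported NA.
#'
#' @param picks a \linkS4class{PickSet} or data.frame with columns x, y.
#' @param truth data.frame with columns x, y (and optionally k, phi, used
#'   by downstream parameter-recovery checks via the returned matches).
#' @param matchRadius maximum centre distance (pixels) for a match; a
#'   common choice is a quarter of the particle diameter.
#' @return a \linkS4class{PickingEval}.
#' @examples
#' truth <- data.frame(x = c(10, 50), y = c(10, 50))
#' found <- data.frame(x = c(10.5, 80), y = c(9.5, 80))
#' evaluatePicking(found, truth, matchRadius = 5)  # TP 1, FP 1, FN 1
#' @export
evaluatePicking <- function(picks, truth, matchRadius) {
  if (matchRadius <= 0) stop("matchRadius must be positive", call. = FALSE)
  pp <- if (is(picks, "PickSet")) picks(picks) else picks
  nP <- nrow(pp); nT <- nrow(truth)
  pairs <- NULL
  if (nP > 0L && nT > 0L) {
    dx <- outer(pp$x, truth$x, "-")
    dy <- outer(pp$y, truth$y, "-")
    d <- sqrt(dx^2 + dy^2)
    idx <- which(d <= matchRadius, arr.ind = TRUE)
    if (nrow(idx)) {
      pairs <- data.frame(pick = idx[, 1L], truth = idx[, 2L],
                          distance = d[idx])
      pairs <- pairs[order(pairs$distance, pairs$pick, pairs$truth), ,
                     drop = FALSE]
    }
  }
  matchedP <- logical(nP); matchedT <- logical(nT)
  acc <- data.frame(pick = integer(0), truth = integer(0),
                    distance = numeric(0))
  if (!is.null(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      p <- pairs$pick[i]; t <- pairs$truth[i]
      if (!matchedP[p] && !matchedT[t]) {
        matchedP[p] <- TRUE; matchedT[t] <- TRUE
        acc <- rbind(acc, pairs[i, , drop = FALSE])
      }
    }
  }
  tp <- sum(matchedP); fp <- nP - tp; fn <- nT - sum(matchedT)
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  fdr <- if (tp + fp > 0L) fp / (tp + fp) else NA_real_
  rownames(acc) <- NULL
  new("PickingEval", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), recall = recall, precision = precision,
      fdr = fdr, matches = acc)
}

#' Recall/precision/FDR curves over a threshold grid
#'
#' Simulates a micrograph (or uses a supplied one), builds the FOM maps
#' once, then re-picks at every threshold (seconds per threshold) and
#' scores against ground truth, yielding the data for recall/precision/
#' FDR-vs-threshold curves.
#'
#' @param thresholds numeric vector of picking thresholds.
#' @param sim list from [simulateMicrograph()] (simulated when NULL with
#'   \code{simArgs}).
#' @param simArgs arguments for [simulateMicrograph()] when \code{sim} is
#'   NULL.
#' @param templates \linkS4class{TemplateSet} for picking (defaults to the
#'   analytic disc/rod pair matching \code{simArgs}).
#' @param ctf optional \linkS4class{CtfParams} used for picking (and, if
#'   \code{sim} is NULL, for simulation).
#' @param diameter particle diameter in Angstrom for masks/min distance.
#' @param minDistance minimum inter-particle distance in Angstrom
#'   (default two-thirds of \code{diameter}).
#' @param matchRadius match tolerance in pixels (default a quarter of the
#'   diameter in pixels).
#' @param angularStep angular sampling in degrees.
#' @param lowpassCutoff template low-pass cutoff in Angstrom.
#' @param seed padding seed.
#' @return data.frame with one row per threshold: threshold, nPicks, tp,
#'   fp, fn, recall, precision, fdr.
#' @export
benchmarkSuite <- function(thresholds, sim = NULL, simArgs = list(),
                           templates = NULL, ctf = NULL, diameter,
                           minDistance = NULL, matchRadius = NULL,
                           angularStep = 5, lowpassCutoff = 20,
                           seed = 0L) {
  if (is.null(sim)) sim <- do.call(simulateMicrograph,
                                   c(simArgs, list(ctf = ctf)))
  mic <- sim$micrograph
  ps <- pixelSize(mic)
  if (is.null(templates)) {
    b <- boxSize(sim$masks)
    r <- sim$masks@radius
    templates <- templateSet(list(discTemplate(b, 0.7 * r),
                                  rodTemplate(b, 1.8 * r, 0.7 * r)),
                             pixelSize = ps)
  }
  if (is.null(minDistance)) minDistance <- (2 / 3) * diameter
  if (is.null(matchRadius)) matchRadius <- 0.25 * diameter / ps
  radius <- diameter / (2 * ps)
  masks <- makeMasks(boxSize(templates), radius)
  padded <- padToSquare(mic, seed = seed)
  stats <- localBackgroundStats(padded$micrograph, masks)
  bank <- prepareTemplates(templates, ctf = ctf, masks = masks,
                           cutoff = lowpassCutoff,
                           angles = rotationGrid(angularStep),
                           pixelSize = ps)
  fom <- buildFomMaps(padded$micrograph, bank, stats,
                      origDim = padded$origDim,
                      micrographName = sourcePath(mic), seed = seed)
  rows <- lapply(thresholds, function(thr) {
    pk <- picksFromFomMaps(fom, threshold = thr,
                           minDistance = minDistance / ps)
    ev <- evaluatePicking(pk, sim$truth, matchRadius)
    m <- evalMetrics(ev)
    data.frame(threshold = thr, nPicks = nPicks(pk), tp = m$tp,
               fp = m$fp, fn = m$fn, recall = m$recall,
               precision = m$precision, fdr = m$fdr)
  })
  do.call(rbind, rows)
}
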
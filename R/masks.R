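## Circular particle/background masks and the local normalisation fields.

#' Build complementary circular particle/background masks
#'
#' Splits a square particle box into a particle area Mi (pixels whose
#' centre lies strictly closer than \code{radius} to the box centre) and
#' the complementary background area Mo.  The box centre is at pixel
#' coordinate \code{((boxSize-1)/2, (boxSize-1)/2)}, i.e. between pixels
#' for an even box.
#'
#' @param boxSize box side in pixels.
#' @param radius circle radius R in pixels.
#' @return a \linkS4class{BoxMasks}.
#' @examples
#' m <- makeMasks(64, 24)
#' nInner(m) + nOuter(m) == 64^2
#' @export
makeMasks <- function(boxSize, radius) {
  boxSize <- as.integer(boxSize)
  if (boxSize < 2L) stop("boxSize must be at least 2", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  ctr <- (boxSize - 1) / 2
  d <- (seq_len(boxSize) - 1) - ctr
  dist2 <- outer(d^2, d^2, "+")
  mi <- (dist2 < radius^2) * 1
  mo <- 1 - mi
  nI <- as.integer(sum(mi)); nO <- as.integer(sum(mo))
  if (nI == 0L)
    stop("radius ", radius, " too small: particle mask Mi is empty",
         call. = FALSE)
  if (nO == 0L)
    stop("radius ", radius, " too large: background mask Mo is empty",
         call. = FALSE)
  new("BoxMasks", boxSize = boxSize, radius = radius, mi = mi, mo = mo,
      nInner = nI, nOuter = nO)
}

#' Normalise a particle image by its background statistics
#'
#' Subtracts the mean and divides by the (population) standard deviation of
#' the pixels in the background area Mo, bringing the noise in every
#' extracted particle to mean zero / unit standard deviation regardless of
#' local ice thickness or exposure.
#'
#' @param image square numeric matrix with the same box size as the masks.
#' @param masks a \linkS4class{BoxMasks}.
#' @return normalised image (same shape); by construction its Mo pixels
#'   have mean 0 and standard deviation 1.
#' @export
normalizeParticle <- function(image, masks) {
  stopIfNot2dSquare(image, "particle image")
  if (nrow(image) != masks@boxSize)
    stop("image box (", nrow(image), ") does not match masks box (",
         masks@boxSize, ")", call. = FALSE)
  bg <- image[masks@mo == 1]
  m <- mean(bg)
  s <- popSd(bg)
  if (!is.finite(s) || s <= 1e-12 * max(1, abs(m)))
    stop("cannot normalise particle: background standard deviation is zero",
         call. = FALSE)
  (image - m) / s
}

#' Local background mean/sd fields of a micrograph via FFT
#'
#' For every candidate box position t (0-based top-left corner of the
#' sliding box), computes the mean mu(t) and standard deviation sigma(t)
#' of the micrograph pixels under the background mask Mo:
#' \deqn{\mu(t) = \frac{1}{|Mo|}\sum_{q \in Mo} X(q+t), \qquad
#'   \sigma^2(t) = \frac{1}{|Mo|}\sum_{q \in Mo} X^2(q+t) - \mu^2(t).}
#' Both fields are obtained for all t at once by two FFT cross-correlations
#' with the Mo mask (circular, wrap-around boundary; positions whose box
#' would cross the true micrograph edge are excluded later at peak
#' selection).  Round-off negatives are clamped to zero before the square
#' root, and positions with sigma below 1e-6 of the global micrograph sd
#' are flagged invalid so flat regions can never produce picks.
#'
#' @param x a square \linkS4class{Micrograph} (pad first, see
#'   [padToSquare()]) or a square numeric matrix.
#' @param masks a \linkS4class{BoxMasks} with box not exceeding the
#'   micrograph side.
#' @return a \linkS4class{LocalStatsMaps}.
#' @export
localBackgroundStats <- function(x, masks) {
  X <- if (is(x, "Micrograph")) pixels(x) else x
  stopIfNot2dSquare(X, "micrograph (pad to square first)")
  if (masks@boxSize > nrow(X))
    stop("mask box exceeds micrograph side", call. = FALSE)
  mo <- masks@mo
  fx <- fft2(X)
  ccX <- crossCorrelate(X, mo, fx = fx)
  ccX2 <- crossCorrelate(X^2, mo)
  mu <- ccX / masks@nOuter
  v <- ccX2 / masks@nOuter - mu^2
  v[v < 0] <- 0
  sigma <- sqrt(v)
  floor <- 1e-6 * popSd(X)
  valid <- sigma > floor   # strict: a flat micrograph has floor 0
  new("LocalStatsMaps", mu = mu, sigma = sigma, valid = valid,
      sigmaFloor = floor)
}
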
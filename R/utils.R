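## Shared numeric helpers: FFT cross-correlation, frequency grids,
## sentinels, small constructors.

#' Construct a Micrograph
#'
#' @param pixels numeric matrix (rows = y, cols = x).
#' @param pixelSize Angstrom per pixel.
#' @param sourcePath text identifier.
#' @return a \linkS4class{Micrograph}.
#' @export
micrograph <- function(pixels, pixelSize = 1, sourcePath = "<memory>") {
  new("Micrograph", pixels = pixels, pixelSize = pixelSize,
      sourcePath = sourcePath)
}

#' Construct CTF parameters
#'
#' @param defocusU,defocusV defoci in Angstrom (positive = underfocus).
#' @param astigAngle astigmatism angle in degrees.
#' @param voltage acceleration voltage in kV.
#' @param cs spherical aberration in mm.
#' @param amplitudeContrast amplitude contrast fraction in [0, 1).
#' @param phaseShift constant phase shift in degrees.
#' @return a \linkS4class{CtfParams}.
#' @export
ctfParams <- function(defocusU, defocusV = defocusU, astigAngle = 0,
                      voltage = 300, cs = 2.7, amplitudeContrast = 0.1,
                      phaseShift = 0) {
  new("CtfParams", defocusU = defocusU, defocusV = defocusV,
      astigAngle = astigAngle, voltage = voltage, cs = cs,
      amplitudeContrast = amplitudeContrast, phaseShift = phaseShift)
}

#' Construct a TemplateSet from a list of matrices
#'
#' @param images list of square numeric matrices with equal box size.
#' @param pixelSize Angstrom per pixel.
#' @return a \linkS4class{TemplateSet}.
#' @export
templateSet <- function(images, pixelSize = 1) {
  if (is.matrix(images)) images <- list(images)
  new("TemplateSet", images = images,
      pixelSize = pixelSize,
      boxSize = if (length(images)) as.integer(nrow(images[[1L]])) else 0L)
}

#' Construct a PickSet from a coordinate table
#'
#' @param coords data.frame with columns x, y, k, phi, s (0-based centre
#'   coordinates in pixels, 0-based template index, degrees, similarity).
#' @param micrographName source identifier.
#' @param pixelSize Angstrom per pixel.
#' @param boxSize template box side in pixels, if known.
#' @return a \linkS4class{PickSet}.
#' @export
pickSet <- function(coords = emptyPickFrame(), micrographName = "<memory>",
                    pixelSize = 1, boxSize = NA_integer_) {
  rownames(coords) <- NULL
  new("PickSet", coords = coords, micrographName = micrographName,
      pixelSize = pixelSize, boxSize = as.integer(boxSize))
}

emptyPickFrame <- function() {
  data.frame(x = numeric(0), y = numeric(0), k = integer(0),
             phi = numeric(0), s = numeric(0))
}

## Sentinel marking invalid positions in similarity / FOM maps.  Finite (so
## it survives float32 MRC round trips) and far below any attainable score.
fomSentinel <- function() -1e30
fomSentinelGuard <- function() -1e29

## 2D FFT wrappers.  stats::fft on a matrix is the 2D transform.
fft2 <- function(x) stats::fft(x)
ifft2Real <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

## Circular cross-correlation: cc[i, j] = sum_q X[q + t] A[q] with
## t = (i-1, j-1) and wrap-around, A a small kernel placed at the origin
## corner of an X-sized zero array.  One forward FFT of X may be reused
## across kernels by passing fx = fft2(X).
crossCorrelate <- function(x, kernel, fx = NULL) {
  if (is.null(fx)) fx <- fft2(x)
  big <- matrix(0, nrow(x), ncol(x))
  big[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  ifft2Real(fx * Conj(fft2(big)))
}

## Signed FFT frequency indices for axis length n: 0, 1, ..., n/2, -(n/2-1),
## ..., -1 (even n keeps +n/2 as Nyquist).
fftIndex <- function(n) {
  k <- 0:(n - 1L)
  ifelse(k <= n / 2, k, k - n)
}

## Radial spatial frequency (1/Angstrom) and azimuth (radians) grids for a
## square box, laid out to match R's fft ordering (rows = y, cols = x).
frequencyGrids <- function(n, pixelSize) {
  f1 <- fftIndex(n) / (n * pixelSize)
  fy <- matrix(f1, n, n)        # varies down rows
  fx <- matrix(f1, n, n, byrow = TRUE)
  list(f = sqrt(fx^2 + fy^2), azimuth = atan2(fy, fx))
}

## Average a real transfer function with its point-inverted image so a
## real filter stays exactly Hermitian (matters on the self-conjugate
## Nyquist row/column of even grids under astigmatism).
hermitianSymmetrise <- function(C) {
  n <- nrow(C)
  inv <- c(1L, n:2L)
  (C + C[inv, inv]) / 2
}

## Quantise doubles to the nearest float32, returning doubles.  Used so
## in-memory FOM maps coincide exactly with their MRC (mode 2) files.
quantiseFloat32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                 numeric(), n = length(x), size = 4L)
  dim(out) <- d
  out
}

## Population standard deviation (divide by n, not n-1).
popSd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

stopIfNot2dSquare <- function(img, what = "image") {
  if (!is.matrix(img) || nrow(img) != ncol(img))
    stop(what, " must be a square matrix", call. = FALSE)
}
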
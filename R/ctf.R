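## Contrast transfer function: the standard astigmatic weak-phase model
## with CTFFIND-style parameters.  Templates are modulated by the
## micrograph's CTF so that picking is fully CTF-corrected.

#' Relativistic electron wavelength
#'
#' @param voltage acceleration voltage in kV.
#' @return wavelength in Angstrom.
#' @examples
#' electronWavelength(300)  # ~0.0197 A
#' @export
electronWavelength <- function(voltage) {
  V <- voltage * 1000
  12.2639 / sqrt(V + 0.97845e-6 * V^2)
}

#' Evaluate the CTF at given spatial frequencies
#'
#' Computes \eqn{-[\sqrt{1-Q^2}\sin\chi + Q\cos\chi]} where Q is the
#' amplitude contrast and \eqn{\chi(f,\alpha) = \pi\lambda f^2 \Delta z(\alpha)
#' - \frac{\pi}{2} C_s \lambda^3 f^4 + \delta} is the defocus +
#' spherical-aberration phase aberration with astigmatic defocus
#' \eqn{\Delta z(\alpha) = \frac{1}{2}[\Delta z_U + \Delta z_V +
#' (\Delta z_U - \Delta z_V)\cos 2(\alpha - \alpha_{ast})]} and constant
#' phase shift \eqn{\delta}.  The leading minus sign follows the
#' protein-is-dark convention for raw micrographs; at zero frequency the
#' value is exactly \code{-Q}.
#'
#' @param params a \linkS4class{CtfParams}.
#' @param frequency spatial frequency magnitude(s) in 1/Angstrom (>= 0).
#' @param azimuth azimuth angle(s) in radians (recycled against
#'   \code{frequency}).
#' @return dimensionless CTF value(s).
#' @export
ctfValue <- function(params, frequency, azimuth = 0) {
  lambda <- electronWavelength(params@voltage)
  astig <- params@astigAngle * pi / 180
  dz <- 0.5 * (params@defocusU + params@defocusV +
               (params@defocusU - params@defocusV) * cos(2 * (azimuth - astig)))
  csA <- params@cs * 1e7   # mm -> Angstrom
  chi <- pi * lambda * frequency^2 * dz -
    (pi / 2) * csA * lambda^3 * frequency^4 +
    params@phaseShift * pi / 180
  q <- params@amplitudeContrast
  -(sqrt(1 - q^2) * sin(chi) + q * cos(chi))
}

#' Apply a micrograph's CTF to a template image
#'
#' Multiplies each Fourier coefficient of the (square) template by the CTF
#' at its spatial frequency and azimuth, then transforms back.  The
#' transfer function is symmetrised under point inversion of the frequency
#' before use: on the self-conjugate Nyquist row/column of an even-sized
#' grid (where +n/2 and -n/2 coincide) an astigmatic CTF evaluates
#' differently for the two azimuths, and a real filter must carry their
#' average there.  The output is therefore real by construction.
#'
#' @param template square numeric matrix.
#' @param params a \linkS4class{CtfParams}.
#' @param pixelSize Angstrom per pixel.
#' @param ctfFun optional replacement for [ctfValue()] taking
#'   \code{(params, frequency, azimuth)}; exposed for testing (e.g. a
#'   unit CTF leaves the template unchanged).
#' @return CTF-modulated template (real matrix).
#' @export
applyCtfToTemplate <- function(template, params, pixelSize,
                               ctfFun = ctfValue) {
  stopIfNot2dSquare(template, "template")
  n <- nrow(template)
  g <- frequencyGrids(n, pixelSize)
  ctf <- hermitianSymmetrise(matrix(ctfFun(params, g$f, g$azimuth), n, n))
  ifft2Real(fft2(template) * ctf)
}

#' Strict hard low-pass filter
#'
#' Sets every Fourier coefficient with radial frequency above
#' \code{1/cutoff} exactly to zero and keeps all others unchanged (a hard
#' radial cutoff; no soft edge).  Picking templates are filtered this way
#' (20 Angstrom by convention) to limit reference bias: no spectral power
#' beyond the cutoff can be imprinted on the picks.
#'
#' @param template square numeric matrix.
#' @param cutoff resolution cutoff in Angstrom; must be at least
#'   \code{2 * pixelSize} (Nyquist).
#' @param pixelSize Angstrom per pixel.
#' @return filtered template (real matrix) with exactly zero spectral
#'   power beyond \code{1/cutoff}.
#' @export
lowpassStrict <- function(template, cutoff, pixelSize) {
  stopIfNot2dSquare(template, "template")
  if (cutoff < 2 * pixelSize)
    stop("low-pass cutoff ", cutoff, " A is below the Nyquist limit ",
         2 * pixelSize, " A", call. = FALSE)
  g <- frequencyGrids(nrow(template), pixelSize)
  ft <- fft2(template)
  ft[g$f > 1 / cutoff] <- 0
  ifft2Real(ft)
}

#' Sampled in-plane rotations
#'
#' @param samplingStep angular sampling rate in degrees (5 by convention).
#' @return numeric vector of \code{ceiling(360/samplingStep)} angles
#'   covering [0, 360), starting at 0.
#' @examples
#' length(rotationGrid(5))  # 72
#' @export
rotationGrid <- function(samplingStep = 5) {
  if (samplingStep <= 0 || samplingStep > 360)
    stop("samplingStep must lie in (0, 360]", call. = FALSE)
  nPhi <- ceiling(360 / samplingStep)
  seq(0, by = samplingStep, length.out = nPhi)
}

#' Rotate a template in-plane
#'
#' Rotates about the box centre \code{((box-1)/2, (box-1)/2)} by
#' \code{phi} degrees with bilinear interpolation (source pixels outside
#' the box read as 0).  Positive \code{phi} rotates the image content
#' counterclockwise in the (x right, y down) frame.  Multiples of 90
#' degrees are interpolation-exact.  When masks are supplied, pixels
#' outside the particle area Mi are re-zeroed after interpolation.
#'
#' @param template square numeric matrix.
#' @param phi rotation angle in degrees.
#' @param masks optional \linkS4class{BoxMasks} for re-masking.
#' @return rotated template.
#' @export
rotateTemplate <- function(template, phi, masks = NULL) {
  stopIfNot2dSquare(template, "template")
  b <- nrow(template)
  out <- if (phi %% 360 == 0) template else {
    ctr <- (b - 1) / 2
    th <- phi * pi / 180
    co <- cos(th); si <- sin(th)
    d <- (seq_len(b) - 1) - ctr
    dx <- matrix(d, b, b, byrow = TRUE)   # column offsets
    dy <- matrix(d, b, b)                 # row offsets
    sx <- ctr + co * dx + si * dy         # source x (0-based)
    sy <- ctr - si * dx + co * dy         # source y (0-based)
    x0 <- floor(sx); y0 <- floor(sy)
    wx <- sx - x0; wy <- sy - y0
    at <- function(r0, c0) {              # 0-based lookup, 0 outside
      ok <- r0 >= 0 & r0 < b & c0 >= 0 & c0 < b
      v <- numeric(length(r0))
      idx <- which(ok)
      v[idx] <- template[cbind(r0[idx] + 1L, c0[idx] + 1L)]
      v
    }
    v <- (1 - wy) * ((1 - wx) * at(y0, x0) + wx * at(y0, x0 + 1)) +
      wy * ((1 - wx) * at(y0 + 1, x0) + wx * at(y0 + 1, x0 + 1))
    matrix(v, b, b)
  }
  if (!is.null(masks)) out <- out * masks@mi
  out
}

#' Prepare templates for picking
#'
#' Turns raw (CTF-corrected, i.e. CTF-free) reference images into the
#' rotated picking references: strict low-pass filter, modulation by the
#' micrograph's CTF, masking to the particle area Mi, in-plane rotation at
#' every sampled angle with re-masking, and a final strict low-pass to
#' restore the exact band limit that real-space masking perturbs.  Box
#' sums \eqn{\sum A} and \eqn{\sum A^2} are cached per (template,
#' rotation), and the per-template log expected probability ratio
#' \eqn{\log E\langle R_k\rangle = \sum A_k^2 / (2|Mi|)} is taken from the
#' unrotated reference.
#'
#' @param x a \linkS4class{TemplateSet} (or list of square matrices).
#' @param ctf a \linkS4class{CtfParams}, or NULL to skip CTF modulation.
#' @param masks a \linkS4class{BoxMasks} matching the template box.
#' @param cutoff low-pass cutoff in Angstrom (20 by convention).
#' @param angles rotation angles in degrees, e.g. [rotationGrid()].
#' @param pixelSize Angstrom per pixel (taken from the set when omitted).
#' @return a \linkS4class{TemplateBank}.
#' @export
prepareTemplates <- function(x, ctf = NULL, masks, cutoff = 20,
                             angles = rotationGrid(5), pixelSize = NULL) {
  if (is(x, "TemplateSet")) {
    if (is.null(pixelSize)) pixelSize <- x@pixelSize
    imgs <- x@images
  } else {
    imgs <- if (is.matrix(x)) list(x) else x
    if (is.null(pixelSize)) pixelSize <- 1
  }
  K <- length(imgs)
  if (K < 1L) stop("no templates to prepare", call. = FALSE)
  b <- nrow(imgs[[1L]])
  if (b != masks@boxSize)
    stop("template box (", b, ") does not match masks box (",
         masks@boxSize, ")", call. = FALSE)
  Phi <- length(angles)
  sumA <- matrix(0, K, Phi)
  sumA2 <- matrix(0, K, Phi)
  bank <- vector("list", K)
  for (k in seq_len(K)) {
    base <- lowpassStrict(imgs[[k]], cutoff, pixelSize)
    if (!is.null(ctf)) base <- applyCtfToTemplate(base, ctf, pixelSize)
    base <- base * masks@mi
    rots <- vector("list", Phi)
    for (j in seq_len(Phi)) {
      a <- rotateTemplate(base, angles[j], masks)
      a <- lowpassStrict(a, cutoff, pixelSize)
      rots[[j]] <- a
      sumA[k, j] <- sum(a)
      sumA2[k, j] <- sum(a^2)
    }
    bank[[k]] <- rots
  }
  logE <- sumA2[, 1L] / (2 * masks@nInner)
  new("TemplateBank", images = bank, angles = angles, sumA = sumA,
      sumA2 = sumA2, logE = logE, masks = masks, pixelSize = pixelSize,
      boxSize = as.integer(b), lowpassCutoff = cutoff,
      ctfApplied = !is.null(ctf))
}
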
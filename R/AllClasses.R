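## Central S4 containers.  Validity methods enforce the contracts the rest
## of the package relies on; use the accessors in AllGenerics.R, not @.

#' Micrograph: a single 2D cryo-EM exposure
#'
#' Holds the pixel grid of one micrograph together with its calibrated pixel
#' size.  Pixels are stored as a numeric matrix indexed \code{[row, col]}
#' with 0-based image coordinates \code{(x = col - 1, y = row - 1)} and the
#' origin at the top-left pixel centre.
#'
#' @slot pixels numeric matrix of intensities (arbitrary units).
#' @slot pixelSize pixel size in Angstrom per pixel; must be > 0.
#' @slot sourcePath text identifier (file of origin or a synthetic label).
#'
#' @seealso [readMicrograph()], [writeMicrograph()], [simulateMicrograph()]
#' @export
setClass("Micrograph",
  representation(pixels = "matrix", pixelSize = "numeric",
                 sourcePath = "character"),
  prototype(pixelSize = 1, sourcePath = "<memory>"))

setValidity("Micrograph", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 2L || ncol(p) < 2L) return("micrograph must be at least 2x2")
  if (!all(is.finite(p))) return("micrograph contains non-finite pixels")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) return("pixelSize must be a single positive number")
  TRUE
})

#' CTF parameters of a micrograph
#'
#' The standard astigmatic weak-phase contrast transfer function
#' parameterisation, matching CTFFIND-style estimation output.
#'
#' @slot defocusU,defocusV defoci along the major/minor astigmatism axes in
#'   Angstrom (positive = underfocus).
#' @slot astigAngle angle of the major axis in degrees.
#' @slot voltage acceleration voltage in kV.
#' @slot cs spherical aberration in mm.
#' @slot amplitudeContrast amplitude contrast fraction Q in [0, 1).
#' @slot phaseShift additional constant phase shift in degrees (phase plate).
#'
#' @seealso [ctfParams()], [ctfValue()], [applyCtfToTemplate()]
#' @export
setClass("CtfParams",
  representation(defocusU = "numeric", defocusV = "numeric",
                 astigAngle = "numeric", voltage = "numeric", cs = "numeric",
                 amplitudeContrast = "numeric", phaseShift = "numeric"),
  prototype(astigAngle = 0, cs = 0, amplitudeContrast = 0.1, phaseShift = 0))

setValidity("CtfParams", function(object) {
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@defocusU) || !one(object@defocusV))
    return("defocus values must be single finite numbers")
  if (!one(object@voltage) || object@voltage <= 0)
    return("voltage must be positive")
  if (!one(object@cs) || object@cs < 0) return("cs must be >= 0")
  q <- object@amplitudeContrast
  if (!one(q) || q < 0 || q >= 1)
    return("amplitudeContrast must lie in [0, 1)")
  if (!one(object@astigAngle) || !one(object@phaseShift))
    return("angles must be single finite numbers")
  TRUE
})

#' Complementary circular particle/background masks
#'
#' A square particle box is split by a circle of radius R (centred at pixel
#' coordinate ((box-1)/2, (box-1)/2)) into the particle area Mi (inside) and
#' the background area Mo (outside).  |Mi| and |Mo| are the white-pixel
#' counts used throughout the normalisation and similarity formulas.
#'
#' @slot boxSize box side in pixels.
#' @slot radius circle radius in pixels.
#' @slot mi,mo binary (0/1) matrices; mi + mo is the all-ones matrix.
#' @slot nInner,nOuter white-pixel counts of mi and mo.
#'
#' @seealso [makeMasks()]
#' @export
setClass("BoxMasks",
  representation(boxSize = "integer", radius = "numeric",
                 mi = "matrix", mo = "matrix",
                 nInner = "integer", nOuter = "integer"))

setValidity("BoxMasks", function(object) {
  b <- object@boxSize
  if (any(dim(object@mi) != b) || any(dim(object@mo) != b))
    return("mask dimensions must equal boxSize")
  if (!all(object@mi %in% c(0, 1)) || !all(object@mo %in% c(0, 1)))
    return("masks must be binary")
  if (any(object@mi + object@mo != 1))
    return("Mi and Mo must be complementary")
  if (object@nInner != sum(object@mi) || object@nOuter != sum(object@mo))
    return("stored counts disagree with masks")
  if (object@nInner <= 0L || object@nOuter <= 0L)
    return("both masks must be non-empty")
  TRUE
})

#' Local background statistics maps
#'
#' Position-dependent additive and multiplicative normalisation fields
#' mu(t) and sigma(t): at each candidate box position t (top-left corner of
#' the box, 0-based), mu is the mean and sigma the standard deviation of
#' the micrograph pixels under the background mask Mo.  Computed for all t
#' at once by FFT cross-correlation with the Mo mask (circular boundary).
#'
#' @slot mu,sigma numeric matrices with the same shape as the (padded)
#'   micrograph.
#' @slot valid logical matrix; FALSE where sigma fell below the degeneracy
#'   floor (flat regions that must never yield picks).
#' @slot sigmaFloor the floor used (1e-6 x global micrograph sd).
#'
#' @seealso [localBackgroundStats()]
#' @export
setClass("LocalStatsMaps",
  representation(mu = "matrix", sigma = "matrix", valid = "matrix",
                 sigmaFloor = "numeric"))

setValidity("LocalStatsMaps", function(object) {
  if (!identical(dim(object@mu), dim(object@sigma)) ||
      !identical(dim(object@mu), dim(object@valid)))
    return("mu, sigma and valid must share one shape")
  if (any(object@sigma < 0)) return("sigma must be non-negative")
  v <- object@valid
  if (!is.logical(v)) return("valid must be logical")
  if (any(!is.finite(object@mu[v])) || any(!is.finite(object@sigma[v])))
    return("mu/sigma must be finite on valid positions")
  TRUE
})

#' A set of raw (unprepared) picking templates
#'
#' K square reference images sharing one box and pixel size, as read from an
#' MRC stack or generated analytically.  Preparation for picking (low-pass
#' filter, CTF modulation, masking, rotation sampling) turns a TemplateSet
#' into a \linkS4class{TemplateBank}.
#'
#' @slot images list of K numeric square matrices.
#' @slot pixelSize Angstrom per pixel.
#' @slot boxSize box side in pixels.
#'
#' @seealso [readTemplateStack()], [prepareTemplates()]
#' @export
setClass("TemplateSet",
  representation(images = "list", pixelSize = "numeric", boxSize = "integer"))

setValidity("TemplateSet", function(object) {
  if (length(object@images) < 1L) return("template set must hold K >= 1 images")
  b <- object@boxSize
  for (im in object@images) {
    if (!is.matrix(im) || nrow(im) != ncol(im))
      return("templates must be square matrices")
    if (nrow(im) != b) return("all templates must share one box size")
    if (!all(is.finite(im))) return("templates must be finite")
  }
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  TRUE
})

#' Prepared, rotated picking references
#'
#' The result of [prepareTemplates()]: for each template k and each sampled
#' in-plane rotation phi, the low-pass filtered, CTF-modulated, Mi-masked
#' reference image, together with cached box sums (sum A, sum A^2) and the
#' per-template log expected probability ratio log E<Rk> used to scale the
#' similarity metric.
#'
#' @slot images list (length K) of lists (length Phi) of matrices.
#' @slot angles sampled in-plane rotations in degrees, first angle 0.
#' @slot sumA,sumA2 K x Phi matrices of cached box sums.
#' @slot logE length-K vector: log E<Rk> = sum(A_k0^2) / (2 |Mi|) from the
#'   unrotated prepared template.
#' @slot masks the \linkS4class{BoxMasks} used.
#' @slot pixelSize,boxSize geometry; \code{lowpassCutoff} in Angstrom.
#' @slot ctfApplied whether a CTF was applied during preparation.
#' @export
setClass("TemplateBank",
  representation(images = "list", angles = "numeric",
                 sumA = "matrix", sumA2 = "matrix", logE = "numeric",
                 masks = "BoxMasks", pixelSize = "numeric",
                 boxSize = "integer", lowpassCutoff = "numeric",
                 ctfApplied = "logical"))

setValidity("TemplateBank", function(object) {
  K <- length(object@images)
  Phi <- length(object@angles)
  if (K < 1L || Phi < 1L) return("bank must hold K >= 1, Phi >= 1 images")
  if (object@angles[1L] != 0 || is.unsorted(object@angles, strictly = TRUE))
    return("angles must start at 0 and increase strictly")
  if (!identical(dim(object@sumA), c(K, Phi)) ||
      !identical(dim(object@sumA2), c(K, Phi)))
    return("cached sums must be K x Phi")
  if (length(object@logE) != K) return("logE must have one entry per template")
  TRUE
})

#' Figure-of-merit maps for one micrograph
#'
#' Per template k, the best similarity over all sampled in-plane rotations
#' at every position, stored in the overflow-safe log-ratio (exponent)
#' domain and quantised to single precision so that writing to MRC and
#' reading back reproduces peak picking bit-identically.  The rotation
#' achieving the maximum is kept alongside.  Similarity values S are
#' recovered on demand via \code{fomSimilarity()}.
#'
#' @slot expo list (length K) of matrices: max over phi of the log
#'   probability ratio, float32-quantised; invalid positions carry the
#'   sentinel -1e30.
#' @slot phi list (length K) of matrices: argmax rotation in degrees.
#' @slot logE length-K log expected ratios (for converting to S).
#' @slot params list of picking geometry needed to re-pick: original
#'   micrograph dims, padded side, box size, mask radius, angular step,
#'   pixel size, micrograph name, seed.
#' @export
setClass("FomMaps",
  representation(expo = "list", phi = "list", logE = "numeric",
                 params = "list"))

setValidity("FomMaps", function(object) {
  K <- length(object@expo)
  if (K < 1L || length(object@phi) != K || length(object@logE) != K)
    return("expo, phi and logE must have one entry per template")
  for (k in seq_len(K))
    if (!identical(dim(object@expo[[k]]), dim(object@phi[[k]])))
      return("expo and phi maps must share one shape")
  TRUE
})

#' A table of particle picks for one micrograph
#'
#' Coordinates are 0-based pixel positions of the particle centre in the
#' unpadded micrograph frame (x = column, y = row, origin at the top-left
#' pixel centre).  Template indices k are 0-based; phi is the in-plane
#' rotation in degrees; S the similarity at the peak.
#'
#' @slot coords data.frame with columns x, y, k, phi, s.
#' @slot micrographName identifier of the source micrograph.
#' @slot pixelSize Angstrom per pixel.
#' @slot boxSize template box side in pixels (margin bookkeeping).
#'
#' @seealso [autopickMicrograph()], [writePicksStar()], [readPicksStar()]
#' @export
setClass("PickSet",
  representation(coords = "data.frame", micrographName = "character",
                 pixelSize = "numeric", boxSize = "integer"),
  prototype(micrographName = "<memory>", pixelSize = 1, boxSize = NA_integer_))

setValidity("PickSet", function(object) {
  cc <- object@coords
  need <- c("x", "y", "k", "phi", "s")
  if (!all(need %in% names(cc)))
    return(paste("coords must have columns", paste(need, collapse = ", ")))
  if (nrow(cc) > 0L) {
    if (!all(is.finite(cc$s))) return("similarity values must be finite")
    if (!all(is.finite(cc$x)) || !all(is.finite(cc$y)))
      return("coordinates must be finite")
    if (!all(cc$k == floor(cc$k)) || any(cc$k < 0))
      return("template indices must be non-negative integers")
  }
  TRUE
})

#' Picking evaluation against ground truth
#'
#' Confusion counts and derived metrics from one-to-one matching of picks
#' against reference coordinates: recall = TP/(TP+FN),
#' precision = TP/(TP+FP), FDR = FP/(TP+FP) = 1 - precision.  When no
#' picks were made (TP+FP = 0) precision and FDR are undefined and
#' reported as NA.
#'
#' @slot tp,fp,fn integer counts.
#' @slot recall,precision,fdr fractions in [0, 1] (or NA, see above).
#' @slot matches data.frame of accepted (pick, truth) pairs with distances.
#' @export
setClass("PickingEval",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 recall = "numeric", precision = "numeric", fdr = "numeric",
                 matches = "data.frame"))

setValidity("PickingEval", function(object) {
  if (object@tp < 0L || object@fp < 0L || object@fn < 0L)
    return("counts must be non-negative")
  TRUE
})
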
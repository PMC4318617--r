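## Generics, accessors and show methods.

#' @rdname Micrograph-class
#' @param object,x an object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname Micrograph-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname Micrograph-class
#' @export
setGeneric("sourcePath", function(x) standardGeneric("sourcePath"))

#' @describeIn Micrograph-class pixel matrix.
#' @export
setMethod("pixels", "Micrograph", function(x) x@pixels)

#' @describeIn Micrograph-class pixel size in Angstrom.
#' @export
setMethod("pixelSize", "Micrograph", function(x) x@pixelSize)

#' @describeIn Micrograph-class source identifier.
#' @export
setMethod("sourcePath", "Micrograph", function(x) x@sourcePath)

#' @describeIn Micrograph-class dimensions (rows, cols).
#' @export
setMethod("dim", "Micrograph", function(x) dim(x@pixels))

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Micrograph %d x %d px @ %.4g A/px  [%s]\n",
              d[1L], d[2L], object@pixelSize, object@sourcePath))
  r <- range(object@pixels)
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              r[1L], r[2L], mean(object@pixels)))
})

#' @describeIn TemplateSet-class pixel size in Angstrom.
#' @export
setMethod("pixelSize", "TemplateSet", function(x) x@pixelSize)

#' @rdname BoxMasks-class
#' @param x an object.
#' @export
setGeneric("innerMask", function(x) standardGeneric("innerMask"))

#' @rdname BoxMasks-class
#' @export
setGeneric("outerMask", function(x) standardGeneric("outerMask"))

#' @rdname BoxMasks-class
#' @export
setGeneric("nInner", function(x) standardGeneric("nInner"))

#' @rdname BoxMasks-class
#' @export
setGeneric("nOuter", function(x) standardGeneric("nOuter"))

#' @rdname BoxMasks-class
#' @export
setGeneric("boxSize", function(x) standardGeneric("boxSize"))

#' @describeIn BoxMasks-class particle-area mask Mi (binary matrix).
#' @export
setMethod("innerMask", "BoxMasks", function(x) x@mi)

#' @describeIn BoxMasks-class background-area mask Mo (binary matrix).
#' @export
setMethod("outerMask", "BoxMasks", function(x) x@mo)

#' @describeIn BoxMasks-class white-pixel count |Mi|.
#' @export
setMethod("nInner", "BoxMasks", function(x) x@nInner)

#' @describeIn BoxMasks-class white-pixel count |Mo|.
#' @export
setMethod("nOuter", "BoxMasks", function(x) x@nOuter)

#' @describeIn BoxMasks-class box side in pixels.
#' @export
setMethod("boxSize", "BoxMasks", function(x) x@boxSize)

setMethod("show", "BoxMasks", function(object) {
  cat(sprintf("BoxMasks: box %d px, R %.3g px, |Mi| = %d, |Mo| = %d\n",
              object@boxSize, object@radius, object@nInner, object@nOuter))
})

#' @describeIn TemplateSet-class number of templates K.
#' @export
setMethod("length", "TemplateSet", function(x) length(x@images))

#' @rdname TemplateSet-class
#' @param x an object.
#' @export
setGeneric("templateImages", function(x) standardGeneric("templateImages"))

#' @describeIn TemplateSet-class list of template matrices.
#' @export
setMethod("templateImages", "TemplateSet", function(x) x@images)

#' @describeIn TemplateSet-class box side in pixels.
#' @export
setMethod("boxSize", "TemplateSet", function(x) x@boxSize)

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet: K = %d, box %d px @ %.4g A/px\n",
              length(object@images), object@boxSize, object@pixelSize))
})

#' @describeIn TemplateBank-class number of templates K.
#' @export
setMethod("length", "TemplateBank", function(x) length(x@images))

#' @rdname TemplateBank-class
#' @param x an object.
#' @export
setGeneric("rotationAngles", function(x) standardGeneric("rotationAngles"))

#' @describeIn TemplateBank-class sampled in-plane rotations (degrees).
#' @export
setMethod("rotationAngles", "TemplateBank", function(x) x@angles)

#' @rdname TemplateBank-class
#' @param k template index (1-based).
#' @param phiIndex rotation index (1-based).
#' @export
setGeneric("bankImage", function(x, k, phiIndex) standardGeneric("bankImage"))

#' @describeIn TemplateBank-class one prepared reference image.
#' @export
setMethod("bankImage", "TemplateBank",
          function(x, k, phiIndex) x@images[[k]][[phiIndex]])

setMethod("show", "TemplateBank", function(object) {
  cat(sprintf(
    "TemplateBank: K = %d templates x Phi = %d rotations, box %d px\n",
    length(object@images), length(object@angles), object@boxSize))
  cat(sprintf("  lowpass %.3g A, CTF %s, log E<Rk>: %s\n",
              object@lowpassCutoff,
              if (object@ctfApplied) "applied" else "not applied",
              paste(sprintf("%.4g", object@logE), collapse = ", ")))
})

#' @rdname PickSet-class
#' @param x an object.
#' @export
setGeneric("picks", function(x) standardGeneric("picks"))

#' @rdname PickSet-class
#' @export
setGeneric("nPicks", function(x) standardGeneric("nPicks"))

#' @rdname PickSet-class
#' @export
setGeneric("micrographName", function(x) standardGeneric("micrographName"))

#' @describeIn PickSet-class the pick table (data.frame x, y, k, phi, s).
#' @export
setMethod("picks", "PickSet", function(x) x@coords)

#' @describeIn PickSet-class number of picks.
#' @export
setMethod("nPicks", "PickSet", function(x) nrow(x@coords))

#' @describeIn PickSet-class source micrograph identifier.
#' @export
setMethod("micrographName", "PickSet", function(x) x@micrographName)

#' @describeIn PickSet-class pixel size in Angstrom.
#' @export
setMethod("pixelSize", "PickSet", function(x) x@pixelSize)

setMethod("show", "PickSet", function(object) {
  cat(sprintf("PickSet: %d picks from %s\n",
              nrow(object@coords), object@micrographName))
  if (nrow(object@coords) > 0L) {
    cat(sprintf("  S range [%.4g, %.4g]; templates used: %s\n",
                min(object@coords$s), max(object@coords$s),
                paste(sort(unique(object@coords$k)), collapse = ", ")))
    print(utils::head(object@coords, 5L))
    if (nrow(object@coords) > 5L) cat("  ...\n")
  }
})

#' @rdname FomMaps-class
#' @param x an object.
#' @export
setGeneric("fomSimilarity", function(x, k) standardGeneric("fomSimilarity"))

#' @describeIn FomMaps-class best-over-rotations similarity map S for
#'   template \code{k} (1-based), derived from the stored log-ratio map;
#'   invalid positions carry the sentinel.
#' @param k template index (1-based).
#' @export
setMethod("fomSimilarity", "FomMaps", function(x, k) {
  e <- x@expo[[k]]
  s <- expm1(e) / expm1(x@logE[k])
  s[e <= fomSentinelGuard()] <- fomSentinel()
  s
})

#' @describeIn FomMaps-class number of templates K.
#' @export
setMethod("length", "FomMaps", function(x) length(x@expo))

setMethod("show", "FomMaps", function(object) {
  d <- dim(object@expo[[1L]])
  cat(sprintf("FomMaps: K = %d templates, %d x %d positions (%s)\n",
              length(object@expo), d[1L], d[2L],
              object@params$micrographName))
})

setMethod("show", "PickingEval", function(object) {
  cat(sprintf("PickingEval: TP %d, FP %d, FN %d\n",
              object@tp, object@fp, object@fn))
  cat(sprintf("  recall %.4g, precision %.4g, FDR %.4g\n",
              object@recall, object@precision, object@fdr))
})

#' @rdname PickingEval-class
#' @param x an object.
#' @export
setGeneric("evalMetrics", function(x) standardGeneric("evalMetrics"))

#' @describeIn PickingEval-class metrics as a named list.
#' @export
setMethod("evalMetrics", "PickingEval", function(x)
  list(tp = x@tp, fp = x@fp, fn = x@fn, recall = x@recall,
       precision = x@precision, fdr = x@fdr))

#' @rdname PickingEval-class
#' @export
setGeneric("evalMatches", function(x) standardGeneric("evalMatches"))

#' @describeIn PickingEval-class accepted (pick, truth) pairs.
#' @export
setMethod("evalMatches", "PickingEval", function(x) x@matches)
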
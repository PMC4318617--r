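## MRC2014 image/stack reader and writer (mode 2, 32-bit float).
## Only the header words the picker needs are interpreted; everything is
## validated rather than silently reinterpreted.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC file (image or stack)
#'
#' Low-level reader for MRC2014 mode-2 (float32) files.  Returns the raw
#' pixel data plus the pixel size derived from the header cell dimensions.
#'
#' @param path file path.
#' @return list with \code{data} (matrix for a single image, list of
#'   matrices for a stack), \code{nz} number of sections, and
#'   \code{pixelSize} (Angstrom; NA when the header carries no sampling).
#' @seealso [readMicrograph()], [readTemplateStack()], [writeMRC()]
#' @export
readMRC <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < MRC_HEADER_BYTES)
    stop("not an MRC file (too short for a header): ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, integer(), n = 10L, size = 4L, endian = "little")
  nx <- ints1[1L]; ny <- ints1[2L]; nz <- ints1[3L]; mode <- ints1[4L]
  mx <- ints1[8L]
  cella <- readBin(con, numeric(), n = 3L, size = 4L, endian = "little")
  readBin(con, numeric(), n = 3L, size = 4L, endian = "little")  # cellb
  readBin(con, integer(), n = 3L, size = 4L, endian = "little")  # axis order
  readBin(con, numeric(), n = 3L, size = 4L, endian = "little")  # dmin/max/mean
  ispg <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  nsymbt <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  if (nx <= 0L || ny <= 0L || nz < 0L)
    stop("malformed MRC header (non-positive dimensions) in ", path,
         call. = FALSE)
  if (mode != 2L)
    stop("unsupported MRC mode ", mode, " in ", path,
         " (only mode 2, float32, is supported)", call. = FALSE)
  if (nz == 0L)
    stop("empty MRC stack (nz = 0) in ", path, call. = FALSE)
  if (nsymbt < 0L || sz < MRC_HEADER_BYTES + nsymbt + 4 * as.numeric(nx) * ny * nz)
    stop("malformed MRC file (data shorter than header promises): ", path,
         call. = FALSE)
  invisible(ispg)
  seek(con, MRC_HEADER_BYTES + nsymbt)
  vec <- readBin(con, numeric(), n = nx * ny * nz, size = 4L,
                 endian = "little")
  pixelSize <- if (mx > 0L && cella[1L] > 0) cella[1L] / mx else NA_real_
  perSlice <- nx * ny
  slices <- lapply(seq_len(nz), function(z) {
    # file order is x-fastest; transpose into [row = y, col = x]
    t(matrix(vec[((z - 1L) * perSlice + 1L):(z * perSlice)], nx, ny))
  })
  list(data = if (nz == 1L) slices[[1L]] else slices,
       nz = nz, pixelSize = pixelSize)
}

#' Write an MRC file (image or stack)
#'
#' Writes MRC2014 mode-2 (float32, little-endian) files.  Pixel values are
#' stored in single precision, so a write-then-read cycle quantises doubles
#' once; a second cycle is bit-exact.
#'
#' @param data numeric matrix, or list of equal-sized matrices for a stack.
#' @param path output file path.
#' @param pixelSize Angstrom per pixel recorded in the header cell.
#' @return \code{path}, invisibly.
#' @export
writeMRC <- function(data, path, pixelSize = 1) {
  if (is.matrix(data)) data <- list(data)
  if (!length(data)) stop("refusing to write an empty MRC stack",
                          call. = FALSE)
  nx <- ncol(data[[1L]]); ny <- nrow(data[[1L]]); nz <- length(data)
  for (m in data)
    if (ncol(m) != nx || nrow(m) != ny)
      stop("all stack sections must share one shape", call. = FALSE)
  all <- unlist(lapply(data, function(m) as.numeric(t(m))))  # x fastest
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(c(nx, ny, nz, 2L))                       # dims + mode 2
  wi(c(0L, 0L, 0L))                           # nxstart
  wi(c(nx, ny, nz))                           # sampling mx my mz
  wf(pixelSize * c(nx, ny, nz))               # cella
  wf(c(90, 90, 90))                           # cellb
  wi(c(1L, 2L, 3L))                           # axis order
  wf(c(min(all), max(all), mean(all)))        # dmin dmax dmean
  wi(c(0L, 0L))                               # ispg, nsymbt
  wi(rep(0L, 2L))                             # extra words 25-26
  writeChar("MRCO", con, nchars = 4L, eos = NULL)  # exttyp
  wi(20140L)                                  # nversion
  wi(rep(0L, 21L))                            # remaining extra words
  wf(c(0, 0, 0))                              # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(popSd(all))                              # rms
  wi(0L)                                      # nlabl
  writeBin(raw(800L), con)                    # labels
  writeBin(as.numeric(all), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a micrograph from an MRC file
#'
#' @param path file path to a 2D MRC image (mode 2).
#' @param pixelSize optional override in Angstrom; takes precedence over the
#'   MRC header (headers are frequently wrong in practice).  When neither is
#'   available, 1 A/px is assumed with a warning.
#' @return a \linkS4class{Micrograph}.
#' @examples
#' \dontrun{mic <- readMicrograph("falcon_0001.mrc", pixelSize = 1.77)}
#' @export
readMicrograph <- function(path, pixelSize = NULL) {
  raw <- readMRC(path)
  if (raw$nz != 1L)
    stop("expected a 2D micrograph but ", path, " holds ", raw$nz,
         " sections (3D volume or stack)", call. = FALSE)
  px <- raw$data
  if (anyNA(px) || !all(is.finite(px)))
    stop("micrograph ", path, " contains non-finite pixel values",
         call. = FALSE)
  ps <- if (!is.null(pixelSize)) pixelSize else raw$pixelSize
  if (is.na(ps)) {
    warning("no pixel size in header of ", path, "; assuming 1 A/px")
    ps <- 1
  }
  micrograph(px, pixelSize = ps, sourcePath = path)
}

#' Write a micrograph to an MRC file
#'
#' @param x a \linkS4class{Micrograph}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMicrograph <- function(x, path) {
  writeMRC(pixels(x), path, pixelSize = pixelSize(x))
}

#' Read a template stack from an MRC file
#'
#' Templates are the K reference images correlated against micrographs;
#' they must be square and share one box size.
#'
#' @param path file path to an MRC stack (mode 2) of K >= 1 square images.
#' @param pixelSize optional override in Angstrom (precedence over header).
#' @return a \linkS4class{TemplateSet}.
#' @export
readTemplateStack <- function(path, pixelSize = NULL) {
  raw <- readMRC(path)
  imgs <- if (raw$nz == 1L) list(raw$data) else raw$data
  b <- nrow(imgs[[1L]])
  for (im in imgs) {
    if (nrow(im) != ncol(im))
      stop("templates in ", path, " are not square (",
           nrow(im), " x ", ncol(im), ")", call. = FALSE)
    if (nrow(im) != b)
      stop("templates in ", path, " have mixed box sizes", call. = FALSE)
  }
  ps <- if (!is.null(pixelSize)) pixelSize else raw$pixelSize
  if (is.na(ps)) {
    warning("no pixel size in header of ", path, "; assuming 1 A/px")
    ps <- 1
  }
  templateSet(imgs, pixelSize = ps)
}

#' Write a template stack to an MRC file
#'
#' @param x a \linkS4class{TemplateSet} or list of square matrices.
#' @param path output file path.
#' @param pixelSize Angstrom per pixel (taken from the set when omitted).
#' @return \code{path}, invisibly.
#' @export
writeTemplateStack <- function(x, path, pixelSize = NULL) {
  if (is(x, "TemplateSet")) {
    if (is.null(pixelSize)) pixelSize <- x@pixelSize
    x <- x@images
  }
  if (is.null(pixelSize)) pixelSize <- 1
  writeMRC(x, path, pixelSize = pixelSize)
}
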
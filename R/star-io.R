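## STAR metadata tables: a minimal dialect with named data blocks, each
## holding either key-value pairs or a single loop_.  This covers CTF
## parameter tables, pick coordinates, sorting output and FOM sidecars.

#' Read a STAR file
#'
#' Parses all data blocks of a STAR file.  Each block is returned as a list
#' with \code{fields} (named key-value pairs given as \code{_key value}
#' lines) and \code{table} (a data.frame from the block's \code{loop_},
#' or NULL).  Numeric-looking columns are converted to numeric.
#'
#' @param path file path.
#' @return named list of blocks (names are the \code{data_<name>} labels).
#' @seealso [writeStarFile()], [readPicksStar()], [readCtfStar()]
#' @export
readStarFile <- function(path) {
  if (!file.exists(path)) stop("STAR file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", lines)
  blocks <- list()
  i <- 1L
  n <- length(lines)
  skipBlank <- function(i) {
    while (i <= n && !nzchar(trimws(stripped[i]))) i <- i + 1L
    i
  }
  i <- skipBlank(i)
  if (i > n || !startsWith(trimws(stripped[i]), "data_"))
    stop("malformed STAR file ", path, ": expected 'data_' block at line ",
         i, call. = FALSE)
  while (i <= n) {
    i <- skipBlank(i)
    if (i > n) break
    tok <- trimws(stripped[i])
    if (!startsWith(tok, "data_"))
      stop("malformed STAR file ", path, ": unexpected content at line ",
           i, ": '", trimws(lines[i]), "'", call. = FALSE)
    blockName <- sub("^data_", "", tok)
    i <- i + 1L
    fields <- list()
    table <- NULL
    repeat {
      i <- skipBlank(i)
      if (i > n) break
      tok <- trimws(stripped[i])
      if (startsWith(tok, "data_")) break
      if (tok == "loop_") {
        i <- i + 1L
        cols <- character(0)
        while (i <= n && startsWith(trimws(stripped[i]), "_")) {
          cols <- c(cols, sub("^_", "", strsplit(trimws(stripped[i]),
                                                 "\\s+")[[1L]][1L]))
          i <- i + 1L
        }
        if (!length(cols))
          stop("malformed STAR file ", path,
               ": loop_ without column labels at line ", i, call. = FALSE)
        rows <- list()
        while (i <= n) {
          txt <- trimws(stripped[i])
          if (!nzchar(txt)) break
          if (startsWith(txt, "data_") || txt == "loop_" ||
              startsWith(txt, "_")) break
          parts <- strsplit(txt, "\\s+")[[1L]]
          if (length(parts) != length(cols))
            stop("malformed STAR file ", path, ": line ", i, " has ",
                 length(parts), " tokens but the loop declares ",
                 length(cols), " columns", call. = FALSE)
          rows[[length(rows) + 1L]] <- parts
          i <- i + 1L
        }
        if (length(rows)) {
          m <- do.call(rbind, rows)
          table <- as.data.frame(m, stringsAsFactors = FALSE)
        } else {
          table <- as.data.frame(matrix(character(0), 0L, length(cols)),
                                 stringsAsFactors = FALSE)
        }
        names(table) <- cols
        for (jc in seq_along(table)) {
          v <- table[[jc]]
          nv <- suppressWarnings(as.numeric(v))
          if (length(v) && !anyNA(nv)) table[[jc]] <- nv
        }
      } else if (startsWith(tok, "_")) {
        parts <- strsplit(tok, "\\s+")[[1L]]
        if (length(parts) < 2L)
          stop("malformed STAR file ", path, ": key without value at line ",
               i, call. = FALSE)
        key <- sub("^_", "", parts[1L])
        val <- paste(parts[-1L], collapse = " ")
        nv <- suppressWarnings(as.numeric(val))
        fields[[key]] <- if (!is.na(nv)) nv else val
        i <- i + 1L
      } else {
        stop("malformed STAR file ", path, ": unexpected token at line ", i,
             ": '", tok, "'", call. = FALSE)
      }
    }
    blocks[[blockName]] <- list(fields = fields, table = table)
  }
  blocks
}

#' Write a STAR file
#'
#' @param blocks named list of blocks; each block is a list with optional
#'   \code{fields} (named key-value pairs) and \code{table} (data.frame
#'   written as a \code{loop_}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStarFile <- function(blocks, path) {
  fmt <- function(v) {
    # 17 significant digits: doubles survive the text round trip exactly
    if (is.numeric(v)) vapply(v, function(x) sprintf("%.17g", x),
                              character(1L))
    else as.character(v)
  }
  out <- character(0)
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    out <- c(out, paste0("data_", bn), "")
    if (!is.null(b$fields) && length(b$fields)) {
      for (key in names(b$fields))
        out <- c(out, paste0("_", key, "  ", fmt(b$fields[[key]])))
      out <- c(out, "")
    }
    if (!is.null(b$table)) {
      tb <- b$table
      out <- c(out, "loop_",
               sprintf("_%s #%d", names(tb), seq_along(tb)))
      if (nrow(tb)) {
        cols <- lapply(tb, fmt)
        out <- c(out, do.call(paste, cols))
      }
      out <- c(out, "")
    }
  }
  writeLines(out, path)
  invisible(path)
}

requireStarColumns <- function(table, cols, path) {
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("STAR file ", path, " is missing required column(s): ",
         paste(paste0("_", miss), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

## Default pick table column names (common cryo-EM conventions).
PICK_COLUMNS <- c(x = "rlnCoordinateX", y = "rlnCoordinateY",
                  k = "rlnClassNumber", phi = "rlnAnglePsi",
                  s = "rlnAutopickFigureOfMerit")

#' Write particle picks to a STAR file
#'
#' Coordinates are written 0-based with the pick denoting the particle
#' centre (x = column, y = row, origin at the top-left pixel centre);
#' template indices are 0-based.  A \code{data_general} block records the
#' micrograph name, pixel size and box size.
#'
#' @param x a \linkS4class{PickSet}.
#' @param path output file path.
#' @param columns named character vector mapping internal names
#'   (x, y, k, phi, s) to STAR column labels.
#' @return \code{path}, invisibly.
#' @export
writePicksStar <- function(x, path, columns = PICK_COLUMNS) {
  cc <- picks(x)
  tb <- data.frame(cc$x, cc$y, cc$k, cc$phi, cc$s)
  names(tb) <- unname(columns[c("x", "y", "k", "phi", "s")])
  fields <- list(cpMicrographName = micrographName(x),
                 cpPixelSize = pixelSize(x))
  if (!is.na(x@boxSize)) fields$cpBoxSize <- x@boxSize
  writeStarFile(list(general = list(fields = fields),
                     picks = list(table = tb)), path)
}

#' Read particle picks from a STAR file
#'
#' Exact inverse of [writePicksStar()] for coordinates, indices and angles
#' (similarity round-trips within float formatting precision).
#'
#' @param path file path.
#' @param columns column-name mapping as in [writePicksStar()].
#' @return a \linkS4class{PickSet}.
#' @export
readPicksStar <- function(path, columns = PICK_COLUMNS) {
  blocks <- readStarFile(path)
  blk <- NULL
  for (b in blocks) if (!is.null(b$table)) { blk <- b; break }
  if (is.null(blk))
    stop("STAR file ", path, " contains no coordinate loop", call. = FALSE)
  tb <- blk$table
  requireStarColumns(tb, unname(columns), path)
  cc <- data.frame(x = as.numeric(tb[[columns[["x"]]]]),
                   y = as.numeric(tb[[columns[["y"]]]]),
                   k = as.integer(tb[[columns[["k"]]]]),
                   phi = as.numeric(tb[[columns[["phi"]]]]),
                   s = as.numeric(tb[[columns[["s"]]]]))
  fields <- if (!is.null(blocks$general)) blocks$general$fields else list()
  pickSet(cc,
          micrographName = if (!is.null(fields$cpMicrographName))
            as.character(fields$cpMicrographName) else "<unknown>",
          pixelSize = if (!is.null(fields$cpPixelSize))
            as.numeric(fields$cpPixelSize) else 1,
          boxSize = if (!is.null(fields$cpBoxSize))
            as.integer(fields$cpBoxSize) else NA_integer_)
}

CTF_COLUMNS <- c(name = "rlnMicrographName", du = "rlnDefocusU",
                 dv = "rlnDefocusV", angle = "rlnDefocusAngle",
                 kv = "rlnVoltage", cs = "rlnSphericalAberration",
                 q = "rlnAmplitudeContrast", ps = "rlnPhaseShift")

#' Read per-micrograph CTF parameters from a STAR table
#'
#' Expects CTFFIND3-style values: defocus U/V in Angstrom, astigmatism
#' angle in degrees, voltage in kV, Cs in mm, amplitude contrast fraction;
#' an optional phase-shift column (degrees) defaults to 0.
#'
#' @param path file path.
#' @return named list of \linkS4class{CtfParams}, one per micrograph,
#'   names taken from the micrograph-name column.
#' @export
readCtfStar <- function(path) {
  blocks <- readStarFile(path)
  blk <- NULL
  for (b in blocks) if (!is.null(b$table)) { blk <- b; break }
  if (is.null(blk))
    stop("STAR file ", path, " contains no CTF loop", call. = FALSE)
  tb <- blk$table
  requireStarColumns(tb, unname(CTF_COLUMNS[c("name", "du", "dv", "angle",
                                              "kv", "cs", "q")]), path)
  hasPhase <- CTF_COLUMNS[["ps"]] %in% names(tb)
  out <- lapply(seq_len(nrow(tb)), function(i) {
    ctfParams(defocusU = as.numeric(tb[[CTF_COLUMNS[["du"]]]][i]),
              defocusV = as.numeric(tb[[CTF_COLUMNS[["dv"]]]][i]),
              astigAngle = as.numeric(tb[[CTF_COLUMNS[["angle"]]]][i]),
              voltage = as.numeric(tb[[CTF_COLUMNS[["kv"]]]][i]),
              cs = as.numeric(tb[[CTF_COLUMNS[["cs"]]]][i]),
              amplitudeContrast = as.numeric(tb[[CTF_COLUMNS[["q"]]]][i]),
              phaseShift = if (hasPhase)
                as.numeric(tb[[CTF_COLUMNS[["ps"]]]][i]) else 0)
  })
  names(out) <- as.character(tb[[CTF_COLUMNS[["name"]]]])
  out
}

#' Write a CTF parameter STAR table
#'
#' @param params named list of \linkS4class{CtfParams} (names are
#'   micrograph identifiers).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCtfStar <- function(params, path) {
  tb <- data.frame(
    name = names(params),
    du = vapply(params, function(p) p@defocusU, numeric(1L)),
    dv = vapply(params, function(p) p@defocusV, numeric(1L)),
    angle = vapply(params, function(p) p@astigAngle, numeric(1L)),
    kv = vapply(params, function(p) p@voltage, numeric(1L)),
    cs = vapply(params, function(p) p@cs, numeric(1L)),
    q = vapply(params, function(p) p@amplitudeContrast, numeric(1L)),
    ps = vapply(params, function(p) p@phaseShift, numeric(1L)))
  names(tb) <- unname(CTF_COLUMNS)
  writeStarFile(list(ctf = list(table = tb)), path)
}
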
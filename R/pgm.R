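# Netpbm PGM (Portable Gray Map) reader/writer.  Angiogram patch databases in
# this domain ship as 64x64 PGM files; both the ASCII (P2) and binary (P5)
# dialects are supported, with header comments tolerated anywhere and
# two-byte big-endian samples when maxval > 255.

#' Construct a grayscale image
#'
#' @param pixels integer matrix of intensities, row-major with origin at the
#'   top-left (rows = image rows).
#' @param maxval maximum representable intensity, 255 or 65535.
#' @return An object of class `gray_image` with fields `pixels` and `maxval`.
#' @export
gray_image <- function(pixels, maxval = 255L) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop_ssfs("image must have at least one row and one column",
              class = "pgm_error")
  }
  if (!maxval %in% c(255L, 65535L)) {
    stop_ssfs("maxval must be 255 or 65535, got %s", maxval,
              class = "pgm_error")
  }
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > maxval) {
    stop_ssfs("pixel values must lie in [0, %d]", maxval, class = "pgm_error")
  }
  structure(list(pixels = pixels, maxval = as.integer(maxval)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, maxval %d>\n",
              nrow(x$pixels), ncol(x$pixels), x$maxval))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

# Pull the next whitespace-delimited token out of a raw PGM header, skipping
# '#' comments.  Returns the token and the offset just past it.
.pgm_next_token <- function(raw, pos) {
  n <- length(raw)
  repeat {
    while (pos <= n && raw[pos] %in% as.raw(c(9L, 10L, 13L, 32L))) {
      pos <- pos + 1L
    }
    if (pos <= n && raw[pos] == as.raw(35L)) { # '#'
      while (pos <= n && !raw[pos] %in% as.raw(c(10L, 13L))) pos <- pos + 1L
    } else {
      break
    }
  }
  if (pos > n) {
    stop_ssfs("truncated PGM header at byte offset %d", pos - 1L,
              class = "pgm_parse_error")
  }
  start <- pos
  while (pos <= n && !raw[pos] %in% as.raw(c(9L, 10L, 13L, 32L, 35L))) {
    pos <- pos + 1L
  }
  list(token = rawToChar(raw[start:(pos - 1L)]), pos = pos)
}

#' Read a PGM image
#'
#' Reads both PGM dialects: `P2` (ASCII) and `P5` (binary).  Comments are
#' tolerated anywhere in the header; binary rasters with `maxval > 255` are
#' read as two-byte big-endian samples per the Netpbm standard.
#'
#' @param path path to a `.pgm` file.
#' @return A [gray_image()].
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) {
    stop_ssfs("file not found: %s", path, class = "pgm_error")
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 2L) {
    stop_ssfs("truncated PGM header at byte offset 0",
              class = "pgm_parse_error")
  }
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P5")) {
    stop_ssfs("unsupported PGM magic '%s' at byte offset 0", magic,
              class = "pgm_magic_error")
  }
  tk <- list(pos = 3L)
  hdr <- integer(3)
  for (i in 1:3) {
    tk <- .pgm_next_token(raw, tk$pos)
    val <- suppressWarnings(as.integer(tk$token))
    if (is.na(val)) {
      stop_ssfs("malformed PGM header token '%s' at byte offset %d",
                tk$token, tk$pos - 1L, class = "pgm_parse_error")
    }
    hdr[i] <- val
  }
  width <- hdr[1]; height <- hdr[2]; maxval <- hdr[3]
  if (width < 1L || height < 1L || !maxval %in% c(255L, 65535L)) {
    stop_ssfs("malformed PGM header (width %d, height %d, maxval %d)",
              width, height, maxval, class = "pgm_parse_error")
  }
  npix <- width * height
  if (magic == "P2") {
    pos <- tk$pos
    vals <- integer(npix)
    for (i in seq_len(npix)) {
      tk <- .pgm_next_token(raw, pos)
      v <- suppressWarnings(as.integer(tk$token))
      if (is.na(v)) {
        stop_ssfs("malformed PGM raster token '%s' at byte offset %d",
                  tk$token, pos, class = "pgm_parse_error")
      }
      vals[i] <- v
      pos <- tk$pos
    }
  } else {
    # single whitespace byte after maxval, then the binary raster
    pos <- tk$pos + 1L
    bpp <- if (maxval > 255L) 2L else 1L
    need <- npix * bpp
    if (length(raw) - pos + 1L < need) {
      stop_ssfs("truncated PGM raster at byte offset %d (need %d bytes)",
                length(raw), need, class = "pgm_parse_error")
    }
    bytes <- as.integer(raw[pos:(pos + need - 1L)])
    vals <- if (bpp == 1L) bytes else {
      bytes[seq(1L, need, by = 2L)] * 256L + bytes[seq(2L, need, by = 2L)]
    }
  }
  if (any(vals > maxval)) {
    stop_ssfs("PGM raster value exceeds maxval %d", maxval,
              class = "pgm_parse_error")
  }
  # PGM raster order is row-major from the top-left
  gray_image(matrix(vals, nrow = height, ncol = width, byrow = TRUE), maxval)
}

#' Write a PGM image
#'
#' @param img a [gray_image()].
#' @param path output path.
#' @param format `"P5"` (binary, default) or `"P2"` (ASCII).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, format = c("P5", "P2")) {
  format <- match.arg(format)
  stopifnot(inherits(img, "gray_image"))
  vals <- as.integer(t(img$pixels)) # row-major
  header <- sprintf("%s\n%d %d\n%d\n",
                    format, ncol(img$pixels), nrow(img$pixels), img$maxval)
  if (format == "P2") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    writeChar(paste(vals, collapse = "\n"), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    if (img$maxval > 255L) {
      writeBin(as.raw(c(rbind(vals %/% 256L, vals %% 256L))), con)
    } else {
      writeBin(as.raw(vals), con)
    }
  }
  invisible(path)
}
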
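## Frame input/output and the intensity <-> temperature mapping.
##
## Frames are 8-bit grey rasters stored as PNG (via the png package) or as
## uncompressed 8-bit BMP (minimal codec below; BMP stores rows bottom-up,
## padded to 4-byte boundaries, with a 256-entry grey palette).

#' Convert a temperature to a grey level
#'
#' Applies the linear calibration and rounds to the nearest grey level,
#' clamping to [0, 255]. The returned vector carries a logical
#' \code{"saturated"} attribute marking inputs outside the representable
#' range; clamping (not an error) is the contract so a hot frame degrades
#' gracefully.
#'
#' @param t temperature(s) in degrees Celsius.
#' @param cal a \linkS4class{ThermalCalibration}.
#' @return integer grey level(s) in [0, 255] with attribute
#'   \code{saturated}.
#' @examples
#' intensityOf(9, thermalCalibration(0, 0.1))   # 90
#' @export
intensityOf <- function(t, cal = thermalCalibration()) {
  raw <- (t - cal@tAtZero) / cal@degPerLevel
  level <- as.integer(roundHalfUp(raw))
  sat <- level < 0L | level > 255L
  level <- pmin(pmax(level, 0L), 255L)
  attr(level, "saturated") <- sat
  level
}

#' Convert a grey level to a temperature
#'
#' @param level grey level(s); integer values in [0, 255] (fractional levels
#'   are accepted for interpolated statistics such as a trimmed-mean floor).
#' @param cal a \linkS4class{ThermalCalibration}.
#' @return temperature(s) in degrees Celsius.
#' @examples
#' temperatureOf(90, thermalCalibration(0, 0.1))   # 9
#' @export
temperatureOf <- function(level, cal = thermalCalibration()) {
  if (any(level < 0 | level > 255)) stop("grey level outside [0, 255]")
  cal@tAtZero + level * cal@degPerLevel
}

#' Read a grey-scale thermographic frame
#'
#' Reads an 8-bit grey BMP or PNG raster. Multi-channel images whose
#' channels are identical are collapsed to grey; unequal channels signal a
#' non-grey source and raise an error. The timestamp is parsed from a
#' \code{YYYYMMDD-HHMMSS} pattern in the filename when present, otherwise
#' the file modification time is used.
#'
#' @param path path to a \code{.bmp} or \code{.png} file.
#' @param calibration the \linkS4class{ThermalCalibration} to attach.
#' @return a \linkS4class{ThermalFrame} with pixels exactly as stored.
#' @seealso [writeFrame()]
#' @export
readFrame <- function(path, calibration = thermalCalibration()) {
  if (!file.exists(path)) stop("cannot read frame: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = readPngGrey(path),
    bmp = readBmpGrey(path),
    stop("unsupported frame format: .", ext, " (use .png or .bmp)"))
  thermalFrame(px, calibration, timestamp = frameTimestampFromFile(path),
               frameId = tools::file_path_sans_ext(basename(path)))
}

#' Write a grey-scale thermographic frame
#'
#' @param frame a \linkS4class{ThermalFrame} (or a bare grey-level matrix).
#' @param path output path ending in \code{.png} or \code{.bmp}.
#' @return \code{path}, invisibly.
#' @export
writeFrame <- function(frame, path) {
  px <- if (is(frame, "ThermalFrame")) frame@pixels else frame
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px / 255, path),
    bmp = writeBmpGrey(px, path),
    stop("unsupported frame format: .", ext, " (use .png or .bmp)"))
  invisible(path)
}

frameTimestampFromFile <- function(path) {
  m <- regmatches(basename(path),
                  regexpr("\\d{8}-\\d{6}", basename(path)))
  if (length(m) == 1L) {
    ts <- as.POSIXct(m, format = "%Y%m%d-%H%M%S", tz = "UTC")
    if (!is.na(ts)) return(ts)
  }
  file.mtime(path)
}

readPngGrey <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3L]
    ch <- min(nch, 3L)  # ignore alpha
    for (k in seq_len(ch - 1L))
      if (any(img[, , k] != img[, , k + 1L]))
        stop("multi-channel image with unequal channels: not a grey frame")
    img <- img[, , 1L]
  }
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

## --- minimal 8-bit BMP codec (BITMAPINFOHEADER, BI_RGB) -------------------

readU16 <- function(raw, off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
readU32 <- function(raw, off) {
  sum(as.double(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}

readBmpGrey <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path)
  dataOffset <- readU32(raw, 10)
  width <- readU32(raw, 18)
  height <- readU32(raw, 22)
  bpp <- readU16(raw, 28)
  compression <- readU32(raw, 30)
  if (compression != 0) stop("compressed BMP not supported")
  topDown <- FALSE
  if (height > 2^31) { height <- 2^32 - height; topDown <- TRUE }
  px <- matrix(0L, height, width)
  if (bpp == 8L) {
    stride <- 4 * ceiling(width / 4)
    for (r in seq_len(height)) {
      rowStart <- dataOffset + (r - 1) * stride
      vals <- as.integer(raw[rowStart + seq_len(width)])
      px[if (topDown) r else height - r + 1L, ] <- vals
    }
    ## map through the palette (grey palettes leave values unchanged)
    palOffset <- 54
    palSize <- (dataOffset - palOffset) / 4
    if (palSize >= 1) {
      pal <- matrix(as.integer(raw[palOffset + seq_len(palSize * 4)]),
                    ncol = 4, byrow = TRUE)  # B, G, R, reserved
      if (any(pal[, 1L] != pal[, 2L]) || any(pal[, 1L] != pal[, 3L]))
        stop("BMP palette is not grey-scale: not a grey frame")
      px[] <- pal[px + 1L, 1L]
    }
  } else if (bpp == 24L) {
    stride <- 4 * ceiling(width * 3 / 4)
    for (r in seq_len(height)) {
      rowStart <- dataOffset + (r - 1) * stride
      trip <- matrix(as.integer(raw[rowStart + seq_len(3 * width)]),
                     nrow = 3)
      if (any(trip[1L, ] != trip[2L, ]) || any(trip[1L, ] != trip[3L, ]))
        stop("multi-channel image with unequal channels: not a grey frame")
      px[if (topDown) r else height - r + 1L, ] <- trip[1L, ]
    }
  } else {
    stop("unsupported BMP bit depth: ", bpp)
  }
  px
}

writeBmpGrey <- function(px, path) {
  if (anyNA(px) || any(px < 0) || any(px > 255))
    stop("pixel values must be grey levels in [0, 255]")
  px <- matrix(as.integer(round(px)), nrow(px), ncol(px))
  h <- nrow(px); w <- ncol(px)
  stride <- 4L * as.integer(ceiling(w / 4))
  dataOffset <- 54L + 256L * 4L
  imgSize <- stride * h
  fileSize <- dataOffset + imgSize
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(fileSize); u16(0); u16(0); u32(dataOffset)
  u32(40); u32(w); u32(h); u16(1); u16(8); u32(0); u32(imgSize)
  u32(2835); u32(2835); u32(256); u32(0)
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))
  writeBin(pal, con)
  pad <- as.raw(rep(0L, stride - w))
  for (r in seq(h, 1L)) {  # bottom-up row order
    writeBin(as.raw(px[r, ]), con)
    if (length(pad)) writeBin(pad, con)
  }
  invisible(path)
}
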
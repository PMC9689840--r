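# Minimal DICOM support: uncompressed, explicit VR, little endian.
#
# Covers exactly the tags the measurement pipeline needs (rows/columns, bit
# depth, window centre/width, pixel spacing, pixel data). Files produced by
# write_dicom_minimal() are valid Part-10 files readable by standard DICOM
# toolkits; the reader handles this profile plus implicit-VR fallback for
# the tags it knows.

dcm_tag <- function(group, element) {
  c(as.raw(bitwAnd(group, 0xFF)), as.raw(bitwShiftR(group, 8)),
    as.raw(bitwAnd(element, 0xFF)), as.raw(bitwShiftR(element, 8)))
}

dcm_uint <- function(x, bytes) {
  out <- raw(bytes)
  for (i in seq_len(bytes)) {
    out[i] <- as.raw(bitwAnd(x, 0xFF))
    x <- bitwShiftR(x, 8)
  }
  out
}

# one explicit-VR little-endian data element
dcm_element <- function(group, element, vr, value_raw) {
  len <- length(value_raw)
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(dcm_tag(group, element), charToRaw(vr), raw(2), dcm_uint(len, 4), value_raw)
  } else {
    c(dcm_tag(group, element), charToRaw(vr), dcm_uint(len, 2), value_raw)
  }
}

dcm_str <- function(s) {
  v <- charToRaw(s)
  if (length(v) %% 2 == 1) v <- c(v, charToRaw(" "))
  v
}

#' Write a minimal monochrome DICOM file
#'
#' Stores a 16-bit unsigned grayscale image as an uncompressed,
#' explicit-VR little-endian secondary-capture DICOM file with window
#' centre/width and optional pixel spacing. No identifying tags are
#' written.
#'
#' @param pixels integer matrix of raw intensities in \[0, 65535\].
#' @param path output path.
#' @param window_center,window_width display window (intensity units).
#' @param pixel_spacing optional mm/px (scalar or c(row, col)).
#' @return `path`, invisibly.
#' @export
write_dicom_minimal <- function(pixels, path, window_center, window_width,
                                pixel_spacing = NULL) {
  stopifnot(is.matrix(pixels))
  px <- as.integer(round(clamp(pixels, 0, 65535)))
  h <- nrow(pixels); w <- ncol(pixels)

  # pixel data: row-major (DICOM order), 16-bit little endian
  ord <- as.vector(t(matrix(px, h, w)))
  pix_raw <- writeBin(ord, raw(), size = 2, endian = "little")

  meta_body <- c(
    dcm_element(0x0002, 0x0010, "UI", dcm_str("1.2.840.10008.1.2.1")),
    dcm_element(0x0002, 0x0012, "UI", dcm_str("1.2.826.0.1.3680043.9.9999"))
  )
  meta <- c(
    dcm_element(0x0002, 0x0000, "UL", dcm_uint(length(meta_body), 4)),
    meta_body
  )

  ds <- c(
    dcm_element(0x0008, 0x0060, "CS", dcm_str("OT")),
    if (!is.null(pixel_spacing)) {
      sp <- rep(pixel_spacing, length.out = 2)
      dcm_element(0x0028, 0x0030, "DS",
                  dcm_str(sprintf("%g\\%g", sp[1], sp[2])))
    },
    dcm_element(0x0028, 0x0002, "US", dcm_uint(1, 2)),
    dcm_element(0x0028, 0x0004, "CS", dcm_str("MONOCHROME2")),
    dcm_element(0x0028, 0x0010, "US", dcm_uint(h, 2)),
    dcm_element(0x0028, 0x0011, "US", dcm_uint(w, 2)),
    dcm_element(0x0028, 0x0100, "US", dcm_uint(16, 2)),
    dcm_element(0x0028, 0x0101, "US", dcm_uint(16, 2)),
    dcm_element(0x0028, 0x0102, "US", dcm_uint(15, 2)),
    dcm_element(0x0028, 0x0103, "US", dcm_uint(0, 2)),
    dcm_element(0x0028, 0x1050, "DS", dcm_str(sprintf("%g", window_center))),
    dcm_element(0x0028, 0x1051, "DS", dcm_str(sprintf("%g", window_width))),
    dcm_element(0x7FE0, 0x0010, "OW", pix_raw)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

raw_uint <- function(r) sum(as.integer(r) * 256^(seq_along(r) - 1))

#' Read a minimal DICOM file
#'
#' Sequentially parses uncompressed little-endian DICOM (explicit or
#' implicit VR) and extracts rows, columns, bit depth, window centre/width,
#' pixel spacing and the pixel data. Encapsulated (compressed) transfer
#' syntaxes are rejected.
#'
#' @param path file path.
#' @return list with `pixels` (matrix), `window_center`, `window_width`,
#'   `pixel_spacing` (or NULL when absent).
#' @export
read_dicom_minimal <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140 || !identical(rawToChar(buf[129:132]), "DICM")) {
    stop("not a DICOM part-10 file", call. = FALSE)
  }
  pos <- 133L
  out <- list(window_center = NULL, window_width = NULL, pixel_spacing = NULL)
  rows <- cols <- bits <- NULL
  pix <- NULL
  n <- length(buf)
  short_vrs <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
                 "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL", "US")
  while (pos + 8L <= n + 1L) {
    group <- raw_uint(buf[pos:(pos + 1)])
    element <- raw_uint(buf[(pos + 2):(pos + 3)])
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% short_vrs) {
      len <- raw_uint(buf[(pos + 6):(pos + 7)])
      hdr <- 8L
    } else if (vr %in% c("OB", "OW", "OF", "SQ", "UN", "UT")) {
      len <- raw_uint(buf[(pos + 8):(pos + 11)])
      hdr <- 12L
    } else {
      # implicit VR fallback: 4-byte length directly after the tag
      len <- raw_uint(buf[(pos + 4):(pos + 7)])
      hdr <- 8L
      vr <- "UN"
    }
    if (len == 0xFFFFFFFF) {
      stop("encapsulated/undefined-length DICOM not supported", call. = FALSE)
    }
    val <- if (len > 0) buf[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    key <- sprintf("%04X%04X", group, element)
    txt <- function() trimws(rawToChar(val))
    if (key == "00280010") rows <- raw_uint(val)
    if (key == "00280011") cols <- raw_uint(val)
    if (key == "00280100") bits <- raw_uint(val)
    if (key == "00281050") out$window_center <- as.numeric(strsplit(txt(), "\\\\")[[1]][1])
    if (key == "00281051") out$window_width <- as.numeric(strsplit(txt(), "\\\\")[[1]][1])
    if (key == "00280030") out$pixel_spacing <- as.numeric(strsplit(txt(), "\\\\")[[1]])
    if (key == "7FE00010") pix <- val
    pos <- pos + hdr + len
  }
  if (is.null(rows) || is.null(cols) || is.null(pix)) {
    stop("DICOM file lacks image dimensions or pixel data", call. = FALSE)
  }
  if (rows * cols == 0) stop("zero-sized image", call. = FALSE)
  size <- if (!is.null(bits) && bits <= 8) 1L else 2L
  vals <- readBin(pix, "integer", n = rows * cols, size = size,
                  signed = FALSE, endian = "little")
  out$pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  out
}
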
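# Radiograph container and window-based preprocessing.

#' Construct a radiograph
#'
#' A radiograph couples a 2-D intensity matrix with its display window
#' (centre/width, as stored in DICOM tags) and optional physical pixel
#' spacing. Pixels are stored as read; [normalize_window()] maps them to
#' \[0, 1\] for the downstream models.
#'
#' @param pixels numeric matrix (rows = image rows).
#' @param window_center,window_width display window in intensity units;
#'   `window_width` must be positive when present.
#' @param pixel_spacing mm per pixel (optional scalar or c(row, col)).
#' @param source_id opaque identifier (file path, phantom tag, ...).
#' @return object of class `radiograph`.
#' @export
radiograph <- function(pixels, window_center = NULL, window_width = NULL,
                       pixel_spacing = NULL, source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0) {
    stop("radiograph pixels must be a non-empty numeric matrix", call. = FALSE)
  }
  if (!is.null(window_width) && window_width <= 0) {
    stop("window_width must be positive", call. = FALSE)
  }
  structure(list(pixels = pixels, window_center = window_center,
                 window_width = window_width, pixel_spacing = pixel_spacing,
                 source_id = source_id),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %d x %d px", nrow(x$pixels), ncol(x$pixels)))
  if (!is.null(x$window_center)) {
    cat(sprintf(", window C=%g W=%g", x$window_center, x$window_width))
  }
  if (nzchar(x$source_id)) cat(sprintf(" [%s]", x$source_id))
  cat("\n")
  invisible(x)
}

#' Window-based intensity normalization
#'
#' Linearly maps intensities through the display window and clips to
#' \[0, 1\]: a value `v` becomes `clip((v - (center - width/2)) / width, 0, 1)`,
#' so `v = center` maps to 0.5 and values outside the window saturate.
#'
#' @param pixels numeric array of raw intensities.
#' @param center,width window centre and width; `width` must be positive.
#' @return array of the same shape with values in \[0, 1\].
#' @export
#' @examples
#' normalize_window(3072, center = 2048, width = 4096)  # 0.75
normalize_window <- function(pixels, center, width) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0) {
    stop("window width must be a positive scalar", call. = FALSE)
  }
  clamp((pixels - (center - width / 2)) / width, 0, 1)
}

# normalized [0, 1] pixel matrix of a radiograph, applying its window
# (full-range default when the tags are absent)
normalized_pixels <- function(rg) {
  stopifnot(inherits(rg, "radiograph"))
  wc <- rg$window_center
  ww <- rg$window_width
  if (is.null(wc) || is.null(ww)) {
    lo <- min(rg$pixels); hi <- max(rg$pixels)
    if (hi <= lo) return(matrix(0.5, nrow(rg$pixels), ncol(rg$pixels)))
    wc <- (lo + hi) / 2; ww <- hi - lo
  }
  normalize_window(rg$pixels, wc, ww)
}

#' Load a radiograph from DICOM or PNG
#'
#' The format is sniffed from the file's magic bytes. DICOM window
#' centre/width and pixel spacing tags are honoured when present; PNG files
#' receive full-range window defaults (centre 127.5 / width 255 for 8-bit,
#' centre 32767.5 / width 65535 for 16-bit). No non-geometric DICOM tags are
#' retained.
#'
#' @param path file path.
#' @return a [radiograph()].
#' @export
load_radiograph <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("radiograph file not found: %s", path), call. = FALSE)
  }
  head <- readBin(path, "raw", n = 160)
  is_png <- length(head) >= 8 &&
    identical(head[1:8], as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)))
  is_dcm <- length(head) >= 132 &&
    identical(rawToChar(head[129:132]), "DICM")
  if (is_png) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]  # first channel of RGB(A)
    if (length(px) == 0) stop("zero-sized image", call. = FALSE)
    # png::readPNG scales to [0,1]; recover the integer range from bit depth
    bits <- readBin(path, "raw", n = 25)[25]
    depth <- as.integer(bits)
    maxval <- if (depth == 16) 65535 else 255
    radiograph(px * maxval, window_center = maxval / 2, window_width = maxval,
               source_id = path)
  } else if (is_dcm) {
    d <- read_dicom_minimal(path)
    if (length(d$pixels) == 0) stop("zero-sized image", call. = FALSE)
    radiograph(d$pixels, window_center = d$window_center,
               window_width = d$window_width,
               pixel_spacing = d$pixel_spacing, source_id = path)
  } else {
    stop(sprintf("unreadable image format (not DICOM or PNG): %s", path),
         call. = FALSE)
  }
}

#' Write a \[0, 1\] intensity matrix as an 8-bit PNG file
#'
#' @param pixels numeric matrix (grayscale) or H x W x 3 array (RGB) in
#'   \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_png_image <- function(pixels, path) {
  png::writePNG(clamp(pixels, 0, 1), target = path)
  invisible(path)
}
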
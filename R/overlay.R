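# Transparency overlay: masks, landmarks, axes and angle labels rendered
# into an RGB PNG so every intermediate of a measurement can be inspected.

draw_disc <- function(arr, x, y, radius, col) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  xs <- max(1, round(x) + 1 - radius):min(w, round(x) + 1 + radius)
  ys <- max(1, round(y) + 1 - radius):min(h, round(y) + 1 + radius)
  for (yy in ys) for (xx in xs) {
    if ((xx - 1 - x)^2 + (yy - 1 - y)^2 <= radius^2) {
      arr[yy, xx, ] <- col
    }
  }
  arr
}

draw_segment <- function(arr, p1, p2, col) {
  n <- max(2, ceiling(vnorm(p2 - p1)))
  t <- seq(0, 1, length.out = n)
  xs <- round(p1[1] + t * (p2[1] - p1[1])) + 1
  ys <- round(p1[2] + t * (p2[2] - p1[2])) + 1
  ok <- xs >= 1 & xs <= dim(arr)[2] & ys >= 1 & ys <= dim(arr)[1]
  for (k in 1:3) arr[cbind(ys[ok], xs[ok], k)] <- col[k]
  arr
}

mask_outline <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  er <- mask
  er[2:(h - 1), 2:(w - 1)] <- mask[2:(h - 1), 2:(w - 1)] &
    mask[1:(h - 2), 2:(w - 1)] & mask[3:h, 2:(w - 1)] &
    mask[2:(h - 1), 1:(w - 2)] & mask[2:(h - 1), 3:w]
  mask & !er
}

#' Write a measurement overlay PNG
#'
#' Renders the normalized image with segmentation outlines, detected
#' landmarks, and the mechanical axes / joint lines used for the angles.
#'
#' @param image normalized pixel matrix.
#' @param results list of segmentation results (outlines; optional).
#' @param reports list of `alignment_report`s (axes and centres).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, results = list(), reports = list(), path) {
  arr <- array(rep(clamp(image, 0, 1), 3), c(dim(image), 3))
  palette <- list(femur = c(0.2, 0.6, 1), tibia = c(0.2, 1, 0.4),
                  fibula = c(1, 0.8, 0.2), talus = c(1, 0.4, 0.8),
                  implant_femoral = c(1, 0.3, 0.3),
                  implant_tibial = c(1, 0.5, 0.1))
  for (r in results) {
    col <- palette[[r$label]] %||% c(1, 1, 1)
    ol <- mask_outline(r$mask)
    for (k in 1:3) {
      ch <- arr[, , k]; ch[ol] <- col[k]; arr[, , k] <- ch
    }
  }
  for (rep in reports) {
    ax <- rep$intermediate
    if (is.null(ax)) next
    for (nm in c("head_center", "knee_femoral", "knee_tibial", "ankle_center")) {
      p <- ax[[nm]]
      if (!is_unavailable(p)) arr <- draw_disc(arr, p[1], p[2], 3, c(1, 0, 0))
    }
    if (!is_unavailable(ax$mech_femur) && !is_unavailable(ax$head_center) &&
        !is_unavailable(ax$knee_femoral)) {
      arr <- draw_segment(arr, ax$head_center, ax$knee_femoral, c(1, 1, 0))
    }
    if (!is_unavailable(ax$mech_tibia) && !is_unavailable(ax$knee_tibial) &&
        !is_unavailable(ax$ankle_center)) {
      arr <- draw_segment(arr, ax$knee_tibial, ax$ankle_center, c(1, 1, 0))
    }
  }
  write_png_image(arr, path)
}
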
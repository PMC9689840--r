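# Region-of-interest logic: per-leg grouping of segmentation results,
# fibula/tibia leg-side rule, the four region crops with invertible
# transforms, and model-input preparation (flip to right-leg orientation,
# histogram equalization, 256 x 256 resize).

#' Split segmentation results into per-leg groups
#'
#' Partitions instances by horizontal box-centre clustering into at most two
#' groups (bilateral images). Duplicate labels force a two-group split at
#' the largest gap between sorted x-centres; a group may contain at most one
#' instance per label.
#'
#' @param results list of segmentation results (see [segment()]).
#' @return list of one or two `leg_group` objects (named list `structures`
#'   keyed by label, plus `side`, initially `NA`).
#' @export
split_legs <- function(results) {
  if (length(results) == 0) stop("no segmentation results to group", call. = FALSE)
  labels <- vapply(results, `[[`, "", "label")
  xc <- vapply(results, function(r) unname(box_center(r$box)[1]), numeric(1))
  two <- anyDuplicated(labels) > 0
  if (two) {
    if (diff(range(xc)) < 1) {
      stop("grouping error: duplicate labels with indistinguishable x-centres",
           call. = FALSE)
    }
    ord <- order(xc)
    gaps <- diff(xc[ord])
    cut <- which.max(gaps)
    grp <- integer(length(xc))
    grp[ord[seq_len(cut)]] <- 1L
    grp[ord[-seq_len(cut)]] <- 2L
  } else {
    grp <- rep(1L, length(xc))
  }
  groups <- lapply(sort(unique(grp)), function(g) {
    idx <- which(grp == g)
    labs <- labels[idx]
    if (anyDuplicated(labs) > 0) {
      stop("grouping error: a leg group contains duplicate structure labels",
           call. = FALSE)
    }
    st <- results[idx]
    names(st) <- labs
    structure(list(structures = st, side = NA_character_), class = "leg_group")
  })
  groups
}

#' Determine the leg side from the fibula/tibia relation
#'
#' Under standard radiographic display orientation (patient's right side on
#' the viewer's left) the fibula is lateral to the tibia: a fibula box
#' centre left of the tibia centre indicates a right leg, and vice versa.
#'
#' @param tibia_box,fibula_box half-open boxes.
#' @param standard_display set `FALSE` for non-standard (mirrored) display
#'   orientation, which inverts the rule.
#' @return `"left"` or `"right"`.
#' @export
#' @examples
#' determine_leg_side(box_make(120, 0, 160, 10), box_make(90, 0, 110, 10))
determine_leg_side <- function(tibia_box, fibula_box, standard_display = TRUE) {
  tx <- box_center(tibia_box)[1]
  fx <- box_center(fibula_box)[1]
  if (isTRUE(all.equal(tx, fx))) {
    stop("undetermined leg side: fibula and tibia x-centres coincide",
         call. = FALSE)
  }
  side <- if (fx < tx) "right" else "left"
  if (!standard_display) side <- setdiff(c("left", "right"), side)
  side
}

#' Assign leg sides to groups
#'
#' Applies [determine_leg_side()] to every group; groups whose side cannot
#' be determined get `side = NA` and are skipped downstream, entering the
#' detection-rate denominator.
#'
#' @param groups list of `leg_group` from [split_legs()].
#' @param standard_display see [determine_leg_side()].
#' @return the groups with `side` filled in.
#' @export
assign_leg_sides <- function(groups, standard_display = TRUE) {
  lapply(groups, function(g) {
    tb <- g$structures[["tibia"]]
    fb <- g$structures[["fibula"]]
    g$side <- if (is.null(tb) || is.null(fb)) NA_character_ else {
      tryCatch(determine_leg_side(tb$box, fb$box, standard_display),
               error = function(e) NA_character_)
    }
    g
  })
}

region_unavailable <- function(region, reason) {
  structure(list(region = region, reason = reason),
            class = c("region_unavailable", "unavailable"))
}

#' Build one region crop from a per-leg group
#'
#' Region extents follow the segmentation boxes: the proximal femur crop is
#' the upper quarter of the femur box (full femur x-extent); the native knee
#' crop is the bounding box of the lower eighth of the femur box united with
#' the upper eighth of the tibia box; the TKA knee crop is the bounding box
#' of the two implant-component boxes; the talus crop is the talus box.
#' Each extent is padded by 5% per side and clipped to the image.
#'
#' @param region `"proximal_femur"`, `"knee_native"`, `"knee_tka"` or
#'   `"talus"`.
#' @param leg a `leg_group` from [split_legs()].
#' @param image numeric image matrix (normalized).
#' @return a `region_crop` (pre-resize): list with `region`, `pixels`,
#'   `transform`, `side`; or a `region_unavailable` signal when a required
#'   structure is missing.
#' @export
crop_region <- function(region, leg, image) {
  region <- match.arg(region, REGIONS)
  st <- leg$structures
  need <- switch(region,
    proximal_femur = "femur",
    knee_native = c("femur", "tibia"),
    knee_tka = c("implant_femoral", "implant_tibial"),
    talus = "talus")
  missing <- setdiff(need, names(st))
  if (length(missing) > 0) {
    return(region_unavailable(region, paste0("missing_", missing[1])))
  }
  box <- switch(region,
    proximal_femur = {
      fb <- st$femur$box
      box_make(fb["x0"], fb["y0"], fb["x1"], fb["y0"] + box_height(fb) / 4)
    },
    knee_native = {
      fb <- st$femur$box; tb <- st$tibia$box
      low8 <- box_make(fb["x0"], fb["y1"] - box_height(fb) / 8, fb["x1"], fb["y1"])
      top8 <- box_make(tb["x0"], tb["y0"], tb["x1"], tb["y0"] + box_height(tb) / 8)
      box_union(low8, top8)
    },
    knee_tka = box_union(st$implant_femoral$box, st$implant_tibial$box),
    talus = st$talus$box)

  # 5% padding per side, with an absolute minimum so that landmarks on the
  # edges of small boxes (talus) keep enough image context around them
  pad_x <- max(0.05 * box_width(box), 8)
  pad_y <- max(0.05 * box_height(box), 8)
  x0 <- max(0L, floor(box["x0"] - pad_x))
  y0 <- max(0L, floor(box["y0"] - pad_y))
  x1 <- min(ncol(image), ceiling(box["x1"] + pad_x))
  y1 <- min(nrow(image), ceiling(box["y1"] + pad_y))
  if (x1 - x0 < 2 || y1 - y0 < 2) {
    return(region_unavailable(region, "degenerate_crop"))
  }
  pixels <- image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  structure(list(
    region = region,
    pixels = pixels,
    transform = list(offset = c(unname(x0), unname(y0)), flip = FALSE,
                     crop_size = c(y1 - y0, x1 - x0), out_size = NULL),
    side = leg$side
  ), class = "region_crop")
}

# deterministic contrast-limited histogram equalization on [0, 1] (global,
# midpoint rule). The histogram is clipped at clip_limit times the uniform
# count and the excess redistributed, bounding the slope of the intensity
# map: plain rank equalization would spread the intra-structure noise of a
# nearly two-level crop across the full range and destroy its SNR. A
# constant image maps to a constant.
hist_equalize <- function(mat, n_bins = 256, clip_limit = 4) {
  idx <- pmin(pmax(floor(mat * n_bins) + 1, 1), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  cap <- clip_limit * length(mat) / n_bins
  excess <- sum(pmax(counts - cap, 0))
  counts <- pmin(counts, cap) + excess / n_bins
  cdf <- cumsum(counts) / sum(counts)
  cdf_prev <- c(0, cdf[-n_bins])
  mapped <- (cdf[idx] + cdf_prev[idx]) / 2
  matrix(mapped, nrow(mat), ncol(mat))
}

#' Prepare a region crop as model input
#'
#' Left-leg crops are horizontally flipped so that all landmark models see
#' right-leg orientation (the flip is recorded in the transform and undone
#' at back-projection); deterministic histogram equalization is applied as
#' contrast enhancement; the crop is resized (anisotropically) to 256 x 256
#' with both scale factors recorded in the transform.
#'
#' @param crop a `region_crop` from [crop_region()].
#' @return the crop with 256 x 256 `pixels` and a completed invertible
#'   `transform`.
#' @export
prepare_model_input <- function(crop) {
  stopifnot(inherits(crop, "region_crop"))
  px <- crop$pixels
  if (length(px) == 0 || nrow(px) < 2 || ncol(px) < 2) {
    stop("degenerate (zero-area) crop", call. = FALSE)
  }
  flip <- identical(crop$side, "left")
  if (flip) px <- flip_h(px)
  px <- hist_equalize(px)
  out_size <- c(256L, 256L)
  px <- resize_bilinear(px, out_size)
  crop$pixels <- px
  crop$transform$flip <- flip
  crop$transform$out_size <- out_size
  crop
}

## ---- invertible crop transform --------------------------------------------

# points: n x 2 matrix of 0-based (x, y); prepared-crop frame -> image frame.
# Corner-aligned convention: x_image = offset + unflip(scale * x_crop), with
# unflip(x) = (crop_width - 1) - x when the crop was mirrored.
transform_crop_to_image <- function(points, tf) {
  stopifnot(!is.null(tf$out_size))
  p <- as.matrix(points)
  sx <- tf$crop_size[2] / tf$out_size[2]
  sy <- tf$crop_size[1] / tf$out_size[1]
  x <- p[, 1] * sx
  y <- p[, 2] * sy
  if (isTRUE(tf$flip)) x <- (tf$crop_size[2] - 1) - x
  cbind(x + tf$offset[1], y + tf$offset[2])
}

transform_image_to_crop <- function(points, tf) {
  stopifnot(!is.null(tf$out_size))
  p <- as.matrix(points)
  x <- p[, 1] - tf$offset[1]
  y <- p[, 2] - tf$offset[2]
  if (isTRUE(tf$flip)) x <- (tf$crop_size[2] - 1) - x
  sx <- tf$crop_size[2] / tf$out_size[2]
  sy <- tf$crop_size[1] / tf$out_size[1]
  cbind(x / sx, y / sy)
}
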
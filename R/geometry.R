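# Goniometry: axes and joint lines from role-tagged landmarks and masks,
# and the five alignment parameters with per-parameter availability.
#
# Conventions (fixed, mirror-stable):
#   * mFAmTA = 180 - delta, where delta is the signed varus(+)/valgus(-)
#     deviation between the distally oriented femoral and tibial mechanical
#     axes; neutral alignment = 180, varus < 180.
#   * FSAmTA uses the anatomical femoral shaft axis in place of the
#     mechanical femur axis.
#   * mMPTA  = angle between the proximally oriented tibial mechanical axis
#     and the medially oriented tibial plateau ray.
#   * mLDFA  = angle between the proximally oriented femoral mechanical axis
#     and the laterally oriented femoral condylar joint-line ray.
#   * mLDTA  = angle between the proximally oriented tibial mechanical axis
#     and the laterally oriented ankle-line ray.
# Medial/lateral ray orientation comes from the role-tagged landmark pairs,
# which are side-correct because crops are canonicalized to right-leg
# orientation before landmark placement.

geo_line <- function(point, direction, orientation = NA_character_) {
  list(point = as.numeric(point), direction = unitv(as.numeric(direction)),
       orientation = orientation)
}

unavailable <- function(reason) structure(list(reason = reason), class = "unavailable")

is_unavailable <- function(x) inherits(x, "unavailable")

#' Project crop-frame landmarks back to the image frame
#'
#' Applies the inverse of the crop preparation transform (resize, optional
#' horizontal flip, crop offset) to every landmark; confidences are
#' preserved.
#'
#' @param lms a crop-frame [landmark_set()].
#' @param transform the `transform` element of a [crop_region()] result.
#' @return an image-frame [landmark_set()].
#' @export
project_to_image <- function(lms, transform) {
  if (!identical(lm_frame(lms), "crop")) {
    stop("project_to_image expects a crop-frame landmark set", call. = FALSE)
  }
  pts <- transform_crop_to_image(cbind(lms$x, lms$y), transform)
  out <- lms
  out$x <- pts[, 1]; out$y <- pts[, 2]
  attr(out, "frame") <- "image"
  out
}

#' Algebraic least-squares circle fit (Kasa)
#'
#' Solves the linear system of the Kasa formulation for the circle that
#' minimizes the algebraic residual of `x^2 + y^2 + D x + E y + F = 0`.
#' Used to recover the femoral head centre from head-contour landmarks.
#'
#' @param points n x 2 matrix (n >= 3, not collinear).
#' @return list with `center` (x, y) and `radius`.
#' @export
#' @examples
#' fit_circle(rbind(c(0, 1), c(1, 0), c(0, -1)))$center  # (0, 0)
fit_circle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("circle fit needs at least 3 points", call. = FALSE)
  x <- points[, 1]; y <- points[, 2]
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol) || qr(A)$rank < 3) {
    stop("degenerate circle fit (collinear points)", call. = FALSE)
  }
  cx <- unname(sol[1]) / 2; cy <- unname(sol[2]) / 2
  r2 <- unname(sol[3]) + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) {
    stop("degenerate circle fit", call. = FALSE)
  }
  list(center = c(cx, cy), radius = sqrt(r2))
}

#' Fit the anatomical shaft axis from a femur mask
#'
#' Least-squares line through the per-row centroids of the mask, restricted
#' to the middle diaphyseal span (default rows at 40-70% of the femur
#' bounding box), oriented proximal-to-distal.
#'
#' @param mask logical femur mask (image frame).
#' @param span fraction interval of the bounding-box height to use.
#' @return a line: list(point, direction, orientation).
#' @export
fit_shaft_axis <- function(mask, span = c(0.4, 0.7)) {
  box <- mask_box(mask)
  y0 <- box["y0"] + span[1] * box_height(box)
  y1 <- box["y0"] + span[2] * box_height(box)
  rows <- which(seq_len(nrow(mask)) - 1 >= y0 & seq_len(nrow(mask)) - 1 < y1)
  rows <- rows[rowSums(mask[rows, , drop = FALSE]) > 0]
  if (length(rows) < 50) {
    stop("femur mask too thin for a shaft-axis fit (needs >= 50 rows in span)",
         call. = FALSE)
  }
  xs <- vapply(rows, function(r) {
    cols <- which(mask[r, ])
    mean(cols) - 1
  }, numeric(1))
  ys <- rows - 1
  fit <- stats::lm.fit(cbind(1, ys), xs)
  dirv <- unitv(c(fit$coefficients[2], 1))  # oriented distally (y down)
  geo_line(c(fit$coefficients[1] + fit$coefficients[2] * mean(ys), mean(ys)),
           dirv, "proximal_distal")
}

#' Signed varus/valgus deviation between two distally oriented axes
#'
#' Core angular primitive: the atan2-based signed rotation from the tibial
#' to the femoral axis direction, sign-flipped by leg side so that varus is
#' positive for both legs (mirror stability).
#'
#' @param femoral_dir,tibial_dir distally oriented unit directions (x, y).
#' @param side `"left"` or `"right"`.
#' @return signed deviation in degrees (varus positive).
#' @export
varus_deviation <- function(femoral_dir, tibial_dir, side) {
  s <- if (side == "right") 1 else -1
  s * rot_angle(tibial_dir, femoral_dir)
}

#' Angle between two rays
#'
#' Unsigned angle in degrees within \[0, 180\], computed from the dot
#' product of the unit rays.
#'
#' @param a,b rays given as 2-vectors (directions).
#' @return degrees.
#' @export
signed_angle <- function(a, b) ray_angle(a, b)

## ---- axes construction -----------------------------------------------------

# pull a single role-tagged point; NULL when missing/low-confidence
role_point <- function(lms, role, min_conf) {
  if (is.null(lms)) return(NULL)
  p <- lm_role_points(lms, role, min_conf)
  if (nrow(p) < 1) return(NULL)
  p[1, ]
}

#' Build axes and joint lines for one leg
#'
#' Constructs, from image-frame landmark sets (and the femur mask for the
#' anatomical shaft axis), the centres and lines the five parameters are
#' measured from: femoral head centre (circle fit of the head contour),
#' femoral and tibial knee centres (condylar notch / tibial spines for a
#' native knee, component tangent / tray midpoints for TKA), ankle centre
#' (talus midpoint), the two mechanical axes, the anatomical shaft axis, and
#' the three joint lines. Missing or low-confidence landmarks mark the
#' affected entries unavailable with a machine-readable reason.
#'
#' @param landmarks named list of image-frame [landmark_set()]s (regions
#'   among `proximal_femur`, `knee_native` or `knee_tka`, `talus`).
#' @param femur_mask logical femur mask or NULL.
#' @param side `"left"` or `"right"`.
#' @param shaft_line optional precomputed anatomical shaft axis (list with
#'   `point`, `direction`); when NULL it is fitted from `femur_mask`.
#' @param min_confidence landmarks below this confidence are treated as
#'   missing.
#' @return list of centres and lines (entries may be `unavailable`).
#' @export
build_axes <- function(landmarks, femur_mask = NULL, side,
                       shaft_line = NULL, min_confidence = 0.2) {
  knee_region <- intersect(c("knee_tka", "knee_native"), names(landmarks))[1]
  knee <- if (!is.na(knee_region)) landmarks[[knee_region]] else NULL
  tka <- identical(knee_region, "knee_tka")

  # femoral head centre
  hip <- landmarks[["proximal_femur"]]
  head_pts <- if (is.null(hip)) NULL else lm_role_points(hip, "head_contour", min_confidence)
  head_center <- if (is.null(head_pts) || nrow(head_pts) < 3) {
    unavailable("missing_proximal_femur_landmarks")
  } else {
    tryCatch(fit_circle(head_pts)$center,
             error = function(e) unavailable("degenerate_head_circle_fit"))
  }

  # knee centres and joint line
  c_med <- role_point(knee, "condyle_tangent_medial", min_confidence)
  c_lat <- role_point(knee, "condyle_tangent_lateral", min_confidence)
  knee_femoral <- if (tka) {
    if (is.null(c_med) || is.null(c_lat)) unavailable("missing_knee_landmarks")
    else (c_med + c_lat) / 2
  } else {
    notch <- role_point(knee, "notch_center", min_confidence)
    if (is.null(notch)) unavailable("missing_knee_landmarks") else notch
  }
  knee_tibial <- if (tka) {
    t_med <- role_point(knee, "tray_edge_medial", min_confidence)
    t_lat <- role_point(knee, "tray_edge_lateral", min_confidence)
    if (is.null(t_med) || is.null(t_lat)) unavailable("missing_knee_landmarks")
    else (t_med + t_lat) / 2
  } else {
    s_med <- role_point(knee, "tibial_spine_medial", min_confidence)
    s_lat <- role_point(knee, "tibial_spine_lateral", min_confidence)
    if (is.null(s_med) || is.null(s_lat)) unavailable("missing_knee_landmarks")
    else (s_med + s_lat) / 2
  }

  femoral_joint_line <- if (is.null(c_med) || is.null(c_lat)) {
    unavailable("missing_knee_landmarks")
  } else geo_line(c_med, c_lat - c_med, "medial_lateral")

  plateau_line <- if (tka) {
    t_med <- role_point(knee, "tray_edge_medial", min_confidence)
    t_lat <- role_point(knee, "tray_edge_lateral", min_confidence)
    if (is.null(t_med) || is.null(t_lat)) unavailable("missing_knee_landmarks")
    else geo_line(t_lat, t_med - t_lat, "lateral_medial")
  } else {
    p_med <- role_point(knee, "plateau_edge_medial", min_confidence)
    p_lat <- role_point(knee, "plateau_edge_lateral", min_confidence)
    if (is.null(p_med) || is.null(p_lat)) unavailable("missing_knee_landmarks")
    else geo_line(p_lat, p_med - p_lat, "lateral_medial")
  }

  # ankle centre and line
  tal <- landmarks[["talus"]]
  t_med <- role_point(tal, "talus_medial", min_confidence)
  t_lat <- role_point(tal, "talus_lateral", min_confidence)
  ankle_center <- if (is.null(t_med) || is.null(t_lat)) {
    unavailable(if (is.null(tal)) "missing_talus" else "missing_talus_landmarks")
  } else (t_med + t_lat) / 2
  ankle_line <- if (is_unavailable(ankle_center)) ankle_center else {
    geo_line(t_med, t_lat - t_med, "medial_lateral")
  }

  # mechanical axes (distally oriented)
  mech_femur <- if (is_unavailable(head_center)) head_center
  else if (is_unavailable(knee_femoral)) knee_femoral
  else geo_line(head_center, knee_femoral - head_center, "proximal_distal")

  mech_tibia <- if (is_unavailable(knee_tibial)) knee_tibial
  else if (is_unavailable(ankle_center)) ankle_center
  else geo_line(knee_tibial, ankle_center - knee_tibial, "proximal_distal")

  # anatomical shaft axis
  shaft <- if (!is.null(shaft_line)) {
    geo_line(shaft_line$point, shaft_line$direction, "proximal_distal")
  } else if (!is.null(femur_mask)) {
    tryCatch(fit_shaft_axis(femur_mask),
             error = function(e) unavailable("degenerate_shaft_fit"))
  } else unavailable("missing_femur_mask")

  list(side = side, tka = tka,
       head_center = head_center, knee_femoral = knee_femoral,
       knee_tibial = knee_tibial, ankle_center = ankle_center,
       mech_femur = mech_femur, mech_tibia = mech_tibia, shaft = shaft,
       femoral_joint_line = femoral_joint_line, plateau_line = plateau_line,
       ankle_line = ankle_line)
}

## ---- alignment parameters --------------------------------------------------

# medial ray of a line whose orientation tag records which endpoint order
# it was built with
medial_ray <- function(line) {
  if (line$orientation == "lateral_medial") line$direction else -line$direction
}
lateral_ray <- function(line) -medial_ray(line)

#' Compute the five alignment parameters for one leg
#'
#' Applies the documented angle conventions to an axes bundle from
#' [build_axes()]. Any parameter whose inputs are unavailable is reported
#' unavailable with the originating reason: a missing talus suppresses
#' mMPTA, mFAmTA, FSAmTA and mLDTA (the tibial mechanical axis cannot be
#' built) while mLDFA survives; a missing proximal femur suppresses mLDFA
#' and mFAmTA while FSAmTA is still computed from the mask shaft axis.
#'
#' @param axes output of [build_axes()].
#' @return an `alignment_report`: list with `side`, `angles` (named list;
#'   degrees or `unavailable`), and `intermediate` (the axes bundle).
#' @export
compute_alignment <- function(axes) {
  side <- axes$side
  ang <- list()

  pair <- function(a, b, f) {
    if (is_unavailable(a)) return(a)
    if (is_unavailable(b)) return(b)
    f(a, b)
  }

  ang$mMPTA <- pair(axes$mech_tibia, axes$plateau_line, function(ax, jl) {
    ray_angle(-ax$direction, medial_ray(jl))
  })
  ang$mLDFA <- pair(axes$mech_femur, axes$femoral_joint_line, function(ax, jl) {
    ray_angle(-ax$direction, lateral_ray(jl))
  })
  ang$mLDTA <- pair(axes$mech_tibia, axes$ankle_line, function(ax, jl) {
    ray_angle(-ax$direction, lateral_ray(jl))
  })
  ang$mFAmTA <- pair(axes$mech_femur, axes$mech_tibia, function(f, t) {
    180 - varus_deviation(f$direction, t$direction, side)
  })
  ang$FSAmTA <- pair(axes$shaft, axes$mech_tibia, function(s, t) {
    180 - varus_deviation(s$direction, t$direction, side)
  })

  structure(list(side = side,
                 angles = ang[ANGLE_NAMES],
                 intermediate = axes),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> side=%s\n", x$side))
  for (nm in names(x$angles)) {
    a <- x$angles[[nm]]
    if (is_unavailable(a)) {
      cat(sprintf("  %-7s unavailable (%s)\n", nm, a$reason))
    } else {
      cat(sprintf("  %-7s %.1f deg\n", nm, a))
    }
  }
  invisible(x)
}

# numeric vector of the five angles (NA where unavailable)
report_angles <- function(report) {
  vapply(report$angles, function(a) if (is_unavailable(a)) NA_real_ else a,
         numeric(1))
}

#' Per-parameter detection rates
#'
#' Fraction (and percentage) of legs for which each alignment parameter
#' could be computed.
#'
#' @param reports list of `alignment_report` objects.
#' @return data.frame with columns `parameter`, `available`, `total`,
#'   `fraction`, `percent`.
#' @export
detection_rates <- function(reports) {
  if (length(reports) == 0) stop("no reports given", call. = FALSE)
  avail <- sapply(reports, function(r) !is.na(report_angles(r)))
  data.frame(
    parameter = ANGLE_NAMES,
    available = rowSums(avail),
    total = length(reports),
    fraction = rowSums(avail) / length(reports),
    percent = 100 * rowSums(avail) / length(reports),
    row.names = NULL
  )
}
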
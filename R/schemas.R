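#' Region and landmark vocabulary
#'
#' Four crop regions are measured on a full-leg radiograph: the proximal
#' femur (hip), the knee (native joint or TKA implant, mutually exclusive),
#' and the talus at the ankle. Each region has a fixed, ordered landmark
#' schema; geometry consumes landmarks by *role*, never by name, so the
#' non-role "outline" points can evolve without touching angle code.
#'
#' @format NULL
#' @name landmark-vocabulary
NULL

REGIONS <- c("proximal_femur", "knee_native", "knee_tka", "talus")

SEG_LABELS <- c("femur", "tibia", "fibula", "talus",
                "implant_femoral", "implant_tibial")

BONE_LABELS <- c("femur", "tibia", "fibula", "talus")

ANGLE_NAMES <- c("mMPTA", "mLDFA", "mFAmTA", "mLDTA", "FSAmTA")

#' Landmark schema for a crop region
#'
#' Returns the ordered landmark names and roles for one of the four crop
#' regions: 9 points for the proximal femur (5 femoral-head contour points,
#' 2 neck-waist points, greater and lesser trochanter tips), 20 for the
#' native knee (10 femoral, 10 tibial), 15 for a TKA implant (5 on the
#' femoral component, 10 on the tibial component), and 2 for the talus
#' (medial and lateral superior dome corners).
#'
#' @param region one of `"proximal_femur"`, `"knee_native"`, `"knee_tka"`,
#'   `"talus"`.
#' @return a data.frame with columns `name`, `role` and `part`
#'   (`"femoral"`, `"tibial"` or `NA`), one row per landmark, in canonical
#'   order.
#' @export
#' @examples
#' nrow(landmark_schema("proximal_femur"))  # 9
#' table(landmark_schema("knee_tka")$part)
landmark_schema <- function(region) {
  region <- match.arg(region, REGIONS)
  switch(region,
    proximal_femur = data.frame(
      name = c(paste0("head_", 1:5), "neck_1", "neck_2", "gt_tip", "lt_tip"),
      role = c(rep("head_contour", 5), rep("neck_waist", 2), "gt_tip", "lt_tip"),
      part = NA_character_
    ),
    knee_native = data.frame(
      name = c("fcond_med", "fcond_lat", "fnotch", paste0("fcond_o", 1:7),
               "plat_med", "plat_lat", "spine_med", "spine_lat",
               paste0("plat_o", 1:6)),
      role = c("condyle_tangent_medial", "condyle_tangent_lateral",
               "notch_center", rep("condyle_outline", 7),
               "plateau_edge_medial", "plateau_edge_lateral",
               "tibial_spine_medial", "tibial_spine_lateral",
               rep("plateau_outline", 6)),
      part = c(rep("femoral", 10), rep("tibial", 10))
    ),
    knee_tka = data.frame(
      name = c("ftka_tan_med", "ftka_tan_lat", paste0("ftka_o", 1:3),
               "ttka_tray_med", "ttka_tray_lat", "ttka_stem_prox",
               "ttka_stem_dist", paste0("ttka_o", 1:6)),
      role = c("condyle_tangent_medial", "condyle_tangent_lateral",
               rep("fem_component_outline", 3),
               "tray_edge_medial", "tray_edge_lateral",
               "stem_axis_proximal", "stem_axis_distal",
               rep("tib_component_outline", 6)),
      part = c(rep("femoral", 5), rep("tibial", 10))
    ),
    talus = data.frame(
      name = c("tal_med", "tal_lat"),
      role = c("talus_medial", "talus_lateral"),
      part = NA_character_
    )
  )
}

#' Construct a landmark set
#'
#' A landmark set holds the named, role-tagged 2-D points of one crop
#' region, either in crop-frame or image-frame coordinates.
#'
#' @param region region kind (see [landmark_schema()]).
#' @param points data.frame with columns `name`, `role`, `x`, `y`,
#'   `confidence`; must match the region schema (names, order, roles).
#'   Coordinates may be `NA` for landmarks flagged missing.
#' @param frame `"crop"` or `"image"`.
#' @return an object of class `landmark_set` (a data.frame with attributes
#'   `region` and `frame`).
#' @export
landmark_set <- function(region, points, frame = c("image", "crop")) {
  frame <- match.arg(frame)
  schema <- landmark_schema(region)
  stopifnot(is.data.frame(points),
            all(c("name", "role", "x", "y", "confidence") %in% names(points)))
  if (nrow(points) != nrow(schema) || !identical(points$name, schema$name) ||
      !identical(points$role, schema$role)) {
    stop(sprintf("landmark set does not match the %s schema (%d landmarks)",
                 region, nrow(schema)), call. = FALSE)
  }
  ok <- is.na(points$confidence) | (points$confidence >= 0 & points$confidence <= 1)
  if (!all(ok)) stop("landmark confidences must lie in [0, 1]")
  out <- points[, c("name", "role", "x", "y", "confidence")]
  attr(out, "region") <- region
  attr(out, "frame") <- frame
  class(out) <- c("landmark_set", "data.frame")
  out
}

lm_region <- function(lms) attr(lms, "region")
lm_frame <- function(lms) attr(lms, "frame")

# points of a given role as an n x 2 matrix (x, y), dropping low-confidence
# or missing landmarks
lm_role_points <- function(lms, role, min_confidence = 0) {
  sel <- lms$role == role & !is.na(lms$x) & !is.na(lms$y) &
    (is.na(lms$confidence) | lms$confidence >= min_confidence)
  cbind(lms$x[sel], lms$y[sel])
}
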
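# End-to-end measurement workflow: preprocess -> segment -> split legs ->
# side -> region crops -> landmarks (TKA-aware) -> back-projection ->
# angles, with per-parameter detection-rate accounting. The oracle path
# substitutes ground-truth segmentations/landmarks (and the analytic shaft
# axis) to isolate the deterministic stages.

#' Measure one leg group
#'
#' @param group a `leg_group` with side assigned (see [assign_leg_sides()]).
#' @param image normalized pixel matrix.
#' @param models named list of models (`proximal_femur`, `knee_native`,
#'   `knee_tka`, `talus`) for the trained path; ignored in oracle mode.
#' @param oracle_leg a `leg_ground_truth` to draw landmarks and the shaft
#'   axis from (oracle mode), or NULL.
#' @param min_confidence landmark-confidence gate.
#' @param suppress_regions regions whose landmarks are withheld (used to
#'   exercise the availability logic).
#' @return an `alignment_report`.
#' @export
measure_leg_group <- function(group, image, models = NULL, oracle_leg = NULL,
                              min_confidence = 0.2,
                              suppress_regions = character()) {
  if (is.na(group$side)) {
    axes <- list(side = NA_character_, tka = FALSE,
                 head_center = unavailable("undetermined_side"),
                 knee_femoral = unavailable("undetermined_side"),
                 knee_tibial = unavailable("undetermined_side"),
                 ankle_center = unavailable("undetermined_side"),
                 mech_femur = unavailable("undetermined_side"),
                 mech_tibia = unavailable("undetermined_side"),
                 shaft = unavailable("undetermined_side"),
                 femoral_joint_line = unavailable("undetermined_side"),
                 plateau_line = unavailable("undetermined_side"),
                 ankle_line = unavailable("undetermined_side"))
    return(compute_alignment(axes))
  }
  tka <- all(c("implant_femoral", "implant_tibial") %in% names(group$structures))
  knee_region <- if (tka) "knee_tka" else "knee_native"
  regions <- setdiff(c("proximal_femur", knee_region, "talus"), suppress_regions)

  lms <- list()
  for (region in regions) {
    crop <- crop_region(region, group, image)
    if (inherits(crop, "region_unavailable")) next
    crop <- prepare_model_input(crop)
    set <- if (!is.null(oracle_leg)) {
      oracle_landmarks(oracle_leg, region, crop$transform)
    } else {
      model <- models[[region]]
      if (is.null(model)) next
      detect_landmarks(crop, model, peak_threshold = min_confidence)
    }
    lms[[region]] <- project_to_image(set, crop$transform)
  }

  femur_mask <- if (!is.null(group$structures$femur)) group$structures$femur$mask
  shaft_line <- if (!is.null(oracle_leg)) oracle_leg$shaft_line
  axes <- build_axes(lms, femur_mask = femur_mask, side = group$side,
                     shaft_line = shaft_line, min_confidence = min_confidence)
  compute_alignment(axes)
}

# pair each leg group with the ground-truth leg whose femur mask overlaps
# most (bilateral phantoms)
match_oracle_leg <- function(group, legs) {
  fm <- group$structures$femur
  if (is.null(fm) || length(legs) == 1) return(legs[[1]])
  ious <- vapply(legs, function(l) mask_iou(l$masks$femur, fm$mask), numeric(1))
  legs[[which.max(ious)]]
}

#' Measure a radiograph or phantom
#'
#' Runs the full workflow on one image. In oracle mode (`gt` given, or
#' `input` is a `leg_phantom`) the ground-truth segmentations, landmarks
#' and shaft axis bypass the trained models, isolating the deterministic
#' geometry. For bilateral images every leg is measured separately.
#'
#' @param input a [radiograph()], normalized matrix, or `leg_phantom`.
#' @param models named list with `segmenter` plus per-region landmark
#'   models (trained path).
#' @param oracle use ground truth instead of models.
#' @param min_confidence landmark-confidence gate.
#' @param suppress_structures segmentation labels withheld before grouping
#'   (availability testing).
#' @param suppress_regions landmark regions withheld (availability
#'   testing).
#' @param standard_display display-orientation flag for the side rule.
#' @return list of `alignment_report` (one per detected leg, left-to-right
#'   in the image).
#' @export
measure_image <- function(input, models = NULL, oracle = inherits(input, "leg_phantom"),
                          min_confidence = 0.2,
                          suppress_structures = character(),
                          suppress_regions = character(),
                          standard_display = TRUE) {
  phantom <- if (inherits(input, "leg_phantom")) input
  image <- if (!is.null(phantom)) {
    normalized_pixels(phantom$radiograph)
  } else if (inherits(input, "radiograph")) {
    normalized_pixels(input)
  } else input

  results <- if (oracle) {
    if (is.null(phantom)) stop("oracle mode needs a leg_phantom input", call. = FALSE)
    oracle_segment(phantom)
  } else {
    segment(image, models$segmenter)
  }
  results <- Filter(function(r) !(r$label %in% suppress_structures), results)
  if (length(results) == 0) return(list())
  groups <- assign_leg_sides(split_legs(results), standard_display)
  # stable left-to-right order
  ord <- order(vapply(groups, function(g) {
    min(vapply(g$structures, function(s) unname(s$box["x0"]), numeric(1)))
  }, numeric(1)))
  lapply(groups[ord], function(g) {
    oleg <- if (oracle) match_oracle_leg(g, phantom$legs)
    measure_leg_group(g, image, models = models, oracle_leg = oleg,
                      min_confidence = min_confidence,
                      suppress_regions = suppress_regions)
  })
}

#' Batch measurement with summary and detection rates
#'
#' Processes a batch of inputs (file paths or in-memory objects); a failing
#' image is logged as an all-unavailable entry and never aborts the batch.
#'
#' @param inputs character vector of DICOM/PNG paths, or a list of
#'   [radiograph()] / `leg_phantom` objects.
#' @param models named model list (trained path); NULL for oracle-only
#'   batches of phantoms.
#' @param out_dir when given, writes `summary.csv`, per-image report JSON
#'   and overlay PNGs there.
#' @param ... passed to [measure_image()].
#' @return list with `reports` (flat list), `summary` (data.frame: one row
#'   per image/leg with the five angle columns and availability reasons)
#'   and `rates` (the [detection_rates()] table).
#' @export
run_measure <- function(inputs, models = NULL, out_dir = NULL, ...) {
  if (is.character(inputs)) inputs <- as.list(inputs)
  all_reports <- list()
  rows <- list()
  for (i in seq_along(inputs)) {
    inp <- inputs[[i]]
    id <- if (is.character(inp)) basename(inp) else {
      if (inherits(inp, "leg_phantom")) inp$radiograph$source_id else sprintf("input_%03d", i)
    }
    reports <- tryCatch({
      obj <- if (is.character(inp)) load_radiograph(inp) else inp
      measure_image(obj, models = models, ...)
    }, error = function(e) {
      attr(e, "image_error") <- TRUE
      list(failed_report(conditionMessage(e)))
    })
    for (j in seq_along(reports)) {
      rep <- reports[[j]]
      all_reports[[length(all_reports) + 1L]] <- rep
      ang <- report_angles(rep)
      reasons <- vapply(rep$angles, function(a) {
        if (is_unavailable(a)) a$reason else ""
      }, "")
      rows[[length(rows) + 1L]] <- data.frame(
        image = id, leg = j, side = rep$side %||% NA_character_,
        t(ang), reasons = paste(reasons[reasons != ""], collapse = ";"))
    }
  }
  summary_df <- do.call(rbind, rows)
  rates <- detection_rates(all_reports)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(rates, file.path(out_dir, "detection_rates.csv"),
                     row.names = FALSE)
  }
  list(reports = all_reports, summary = summary_df, rates = rates)
}

failed_report <- function(msg) {
  u <- unavailable(paste0("image_error:", msg))
  structure(list(side = NA_character_,
                 angles = stats::setNames(rep(list(u), 5), ANGLE_NAMES),
                 intermediate = NULL),
            class = "alignment_report")
}
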
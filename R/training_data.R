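# Assembly of phantom-derived training sets for the trainable stages.

#' Build landmark training crops from sampled phantoms
#'
#' Samples `n` phantoms (TKA implants when `region = "knee_tka"`), runs the
#' ground-truth segmentation oracle, cuts and prepares the requested region
#' crop for each leg, and pairs it with the oracle landmark set in the crop
#' frame. This is the standard way to train and evaluate the landmark
#' models without clinical data.
#'
#' @param region region kind.
#' @param n number of phantoms.
#' @param seed sampling seed.
#' @param side passed to [sample_phantom_specs()].
#' @param box_jitter SD (px) of Gaussian jitter applied to every structure
#'   box edge before cropping, emulating the box noise of a trained
#'   segmenter so the landmark models see the crop-frame variability they
#'   will encounter at inference. The default depends on the region: the
#'   knee crop is built from eighth-fractions of two boxes, which amplifies
#'   box-edge errors, so it uses a larger jitter (3 px) than the directly
#'   boxed talus and proximal femur (2 px).
#' @return list with `crops` (prepared `region_crop`s), `landmarks`
#'   (crop-frame [landmark_set()]s) and `phantoms`.
#' @export
phantom_training_crops <- function(region, n, seed = 0L, side = "random",
                                   box_jitter = NULL) {
  region <- match.arg(region, REGIONS)
  if (is.null(box_jitter)) {
    box_jitter <- if (region %in% c("knee_native", "knee_tka")) 3 else 2
  }
  implant <- if (region == "knee_tka") "tka" else "none"
  specs <- sample_phantom_specs(n, seed = seed, side = side, implant = implant)
  crops <- list(); lms <- list(); phantoms <- list()
  for (sp in specs) {
    ph <- generate_phantom(sp)
    groups <- assign_leg_sides(split_legs(oracle_segment(ph)))
    g <- groups[[1]]
    if (box_jitter > 0) {
      g$structures <- lapply(g$structures, function(s) {
        s$box <- s$box + stats::rnorm(4, 0, box_jitter)
        s
      })
    }
    crop <- crop_region(region, g, normalized_pixels(ph$radiograph))
    if (inherits(crop, "region_unavailable")) next
    crop <- prepare_model_input(crop)
    crops[[length(crops) + 1L]] <- crop
    lms[[length(lms) + 1L]] <- oracle_landmarks(ph$legs[[1]], region,
                                                crop$transform)
    phantoms[[length(phantoms) + 1L]] <- ph
  }
  list(crops = crops, landmarks = lms, phantoms = phantoms)
}

#' Build a segmentation training set from sampled phantoms
#'
#' @param n number of phantoms.
#' @param seed sampling seed.
#' @param implant `"none"`, `"tka"` or `"random"`.
#' @return list with `images` (normalized matrices), `masks` (named mask
#'   lists) and `phantoms`.
#' @export
phantom_training_images <- function(n, seed = 0L, implant = "none") {
  specs <- sample_phantom_specs(n, seed = seed, implant = implant)
  phantoms <- lapply(specs, generate_phantom)
  list(
    images = lapply(phantoms, function(p) normalized_pixels(p$radiograph)),
    masks = lapply(phantoms, function(p) p$legs[[1]]$masks),
    phantoms = phantoms
  )
}
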
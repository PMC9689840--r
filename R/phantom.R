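# Synthetic full-leg radiograph phantom with analytic ground truth.
#
# The phantom renders a schematic AP leg (femur, tibia, fibula, talus,
# optional TKA implant) from capsule/disc/polygon primitives, and returns,
# alongside the image, the exact landmark positions, per-structure masks and
# the closed-form values of the five alignment angles implied by the
# generating parameters. It exists so that every downstream stage
# (segmentation, cropping, landmark placement, goniometry) can be exercised
# and tested without clinical data.

#' Specify a synthetic full-leg phantom
#'
#' All linear quantities are in pixels, all angles in degrees. The five
#' generated alignment angles follow from the spec in closed form (see
#' [ground_truth_angles()]): varus is positive, so `knee_varus_valgus = 3`
#' yields a hip-knee-ankle angle (mFAmTA) of 177 degrees.
#'
#' @param side leg side, `"left"` or `"right"` (standard display
#'   orientation: the patient's right leg appears on the viewer's left).
#' @param image_size image height and width `c(H, W)`; defaults to
#'   `c(512, 260)` for unilateral and `c(512, 520)` for bilateral phantoms.
#' @param hip_center femoral head centre `c(x, y)` in image coordinates.
#' @param femur_length,tibia_length mechanical segment lengths (px).
#' @param neck_shaft_offset vector `c(lateral, distal)` from the femoral
#'   head centre to the neck-shaft junction.
#' @param anat_mech_femur_angle angle between the anatomical femoral shaft
#'   axis and the mechanical femur axis (default 6).
#' @param knee_varus_valgus signed deviation between the femoral and tibial
#'   mechanical axes; varus positive.
#' @param femoral_jointline_obliquity,plateau_obliquity,ankle_obliquity
#'   signed tilt of each joint line relative to the perpendicular of its
#'   bone's mechanical axis; must lie within +/-15.
#' @param implant `"none"` or `"tka"`.
#' @param bilateral render two mirrored legs in one frame.
#' @param noise_sd additive Gaussian noise SD on the \[0, 1\] intensity
#'   scale.
#' @param blur_sigma Gaussian blur sigma (px).
#' @param seed integer seed; fully determines the rendered image.
#' @return an object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(knee_varus_valgus = 3)
#' ground_truth_angles(spec)[["mFAmTA"]]  # 177
phantom_spec <- function(side = "right",
                         image_size = NULL,
                         hip_center = NULL,
                         femur_length = 200,
                         tibia_length = 180,
                         neck_shaft_offset = c(20, 6),
                         anat_mech_femur_angle = 6,
                         knee_varus_valgus = 0,
                         femoral_jointline_obliquity = 0,
                         plateau_obliquity = 0,
                         ankle_obliquity = 0,
                         implant = "none",
                         bilateral = FALSE,
                         noise_sd = 0.02,
                         blur_sigma = 1,
                         seed = 1L) {
  side <- match.arg(side, c("left", "right"))
  implant <- match.arg(implant, c("none", "tka"))
  if (is.null(image_size)) image_size <- c(512, if (bilateral) 520 else 260)
  if (is.null(hip_center)) {
    hip_center <- if (bilateral) {
      c(if (side == "right") image_size[2] * 0.25 else image_size[2] * 0.75, 60)
    } else c(image_size[2] / 2, 60)
  }
  spec <- structure(list(
    side = side, image_size = as.numeric(image_size),
    hip_center = as.numeric(hip_center),
    femur_length = femur_length, tibia_length = tibia_length,
    neck_shaft_offset = as.numeric(neck_shaft_offset),
    anat_mech_femur_angle = anat_mech_femur_angle,
    knee_varus_valgus = knee_varus_valgus,
    femoral_jointline_obliquity = femoral_jointline_obliquity,
    plateau_obliquity = plateau_obliquity,
    ankle_obliquity = ankle_obliquity,
    implant = implant, bilateral = isTRUE(bilateral),
    noise_sd = noise_sd, blur_sigma = blur_sigma,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!(spec$femur_length > 0 && spec$tibia_length > 0)) {
    stop("phantom segment lengths must be positive", call. = FALSE)
  }
  obli <- c(spec$femoral_jointline_obliquity, spec$plateau_obliquity,
            spec$ankle_obliquity)
  if (any(abs(obli) > 15)) {
    stop("joint-line obliquities must lie within +/-15 degrees", call. = FALSE)
  }
  if (abs(spec$knee_varus_valgus) > 25) {
    stop("knee varus/valgus outside the supported +/-25 degree range",
         call. = FALSE)
  }
  if (length(spec$image_size) != 2 || any(spec$image_size < 64)) {
    stop("image_size must be c(H, W) with both >= 64", call. = FALSE)
  }
  if (spec$noise_sd < 0 || spec$blur_sigma < 0) {
    stop("noise_sd and blur_sigma must be non-negative", call. = FALSE)
  }
  invisible(spec)
}

#' Closed-form ground-truth angles of a phantom
#'
#' The generating parameters determine the five alignment angles exactly:
#' `mFAmTA = 180 - knee_varus_valgus`,
#' `FSAmTA = 180 - knee_varus_valgus - anat_mech_femur_angle`,
#' `mMPTA = 90 - plateau_obliquity`,
#' `mLDFA = 90 + femoral_jointline_obliquity`,
#' `mLDTA = 90 + ankle_obliquity`.
#'
#' @param spec a [phantom_spec()].
#' @return named numeric vector over the five parameters (degrees).
#' @export
ground_truth_angles <- function(spec) {
  validate_phantom_spec(spec)
  c(mMPTA = 90 - spec$plateau_obliquity,
    mLDFA = 90 + spec$femoral_jointline_obliquity,
    mFAmTA = 180 - spec$knee_varus_valgus,
    mLDTA = 90 + spec$ankle_obliquity,
    FSAmTA = 180 - spec$knee_varus_valgus - spec$anat_mech_femur_angle)[ANGLE_NAMES]
}

# mirror a spec about the vertical image midline (pixel-centre convention)
mirror_phantom_spec <- function(spec) {
  spec$side <- if (spec$side == "right") "left" else "right"
  spec$hip_center[1] <- (spec$image_size[2] - 1) - spec$hip_center[1]
  spec
}

## ---- continuous leg geometry ----------------------------------------------

# All geometry is derived for one leg. sgn = +1 (right leg) or -1 (left);
# lateral x-direction is -sgn under standard display orientation.
leg_geometry <- function(spec, hip_center = spec$hip_center,
                         side = spec$side) {
  sgn <- if (side == "right") 1 else -1
  v <- spec$knee_varus_valgus
  sig <- spec$anat_mech_femur_angle
  phi <- spec$femoral_jointline_obliquity
  rho <- spec$plateau_obliquity
  tau <- spec$ankle_obliquity

  down <- c(0, 1)
  d_F <- as.vector(rot2(sgn * v / 2) %*% down)        # mechanical femur axis, distal
  d_T <- as.vector(rot2(-sgn * v / 2) %*% down)       # mechanical tibia axis, distal
  d_S <- as.vector(rot2(sgn * (v / 2 + sig)) %*% down) # anatomical shaft axis, distal

  H <- hip_center
  K <- H + spec$femur_length * d_F      # centre of the knee joint gap
  g <- 4                                # half joint-gap (px)
  C_f <- K - g * d_F                    # femoral joint-line anchor (notch)
  P_c <- K + g * d_T                    # tibial plateau anchor (knee centre)
  A <- K + spec$tibia_length * d_T      # ankle centre

  # joint-line rays; l* = lateral ray, m* = medial ray
  lat_perp <- function(d) sgn * perp2(d)
  l_f <- unitv(cos(deg2rad(phi)) * lat_perp(d_F) + sin(deg2rad(phi)) * d_F)
  m_t <- unitv(cos(deg2rad(rho)) * (-lat_perp(d_T)) - sin(deg2rad(rho)) * d_T)
  a_l <- unitv(cos(deg2rad(tau)) * lat_perp(d_T) + sin(deg2rad(tau)) * d_T)

  # neck-shaft junction; shaft axis passes through J with direction d_S
  off <- spec$neck_shaft_offset
  J <- H + c(-sgn * off[1], off[2])

  list(sgn = sgn, side = side,
       d_F = d_F, d_T = d_T, d_S = d_S,
       H = H, K = K, C_f = C_f, P_c = P_c, A = A, J = J,
       l_f = l_f, m_t = m_t, a_l = a_l,
       lat_T = lat_perp(d_T))
}

# named list of landmark coordinate matrices per region, in schema order
leg_landmarks <- function(geo, implant) {
  with(geo, {
    # contour angles mirror with the side so that named landmarks mirror
    # exactly under left/right reflection
    base_ang <- c(18, 90, 162, 234, 306)
    head_ang <- deg2rad(if (sgn > 0) base_ang else 180 - base_ang)
    pf <- rbind(
      t(sapply(head_ang, function(a) H + 13 * c(cos(a), sin(a)))),
      H + 0.45 * (J - H),
      H + 0.70 * (J - H),
      J + c(-sgn * 4, -4),
      J + 18 * d_S + c(sgn * 8, 0)
    )
    # talus landmarks sit exactly on the visible corners of the talar dome:
    # the dome's flat superior edge runs through the ankle line, so the
    # corners are at A +/- half-chord along the line (midpoint A)
    w_tal <- sqrt(14^2 - 2^2)
    tal <- rbind(A - w_tal * a_l, A + w_tal * a_l)  # medial, lateral
    out <- list(proximal_femur = pf, talus = tal)
    if (implant == "tka") {
      fem <- rbind(C_f - 18 * l_f, C_f + 18 * l_f,
                   C_f - 12 * l_f - 6 * d_F,
                   C_f - 9 * d_F,
                   C_f + 12 * l_f - 6 * d_F)
      tib <- rbind(P_c + 18 * m_t, P_c - 18 * m_t,
                   P_c + 12 * geo$d_T, P_c + 45 * geo$d_T,
                   P_c + 10 * m_t + 2.5 * d_T, P_c - 10 * m_t + 2.5 * d_T,
                   P_c + 4 * m_t + 2.5 * d_T, P_c - 4 * m_t + 2.5 * d_T,
                   P_c + 25 * d_T, P_c + 35 * d_T)
      out$knee_tka <- rbind(fem, tib)
    } else {
      outl <- rbind(c(-18, 6), c(-10, 12), c(0, 14), c(10, 12), c(18, 6),
                    c(-20, 2), c(20, 2))
      fem <- rbind(C_f - 20 * l_f, C_f + 20 * l_f, C_f,
                   t(apply(outl, 1, function(ab) C_f + ab[1] * l_f - ab[2] * d_F)))
      poutl <- rbind(c(-18, 5), c(-9, 9), c(0, 11), c(9, 9), c(18, 5), c(0, 4))
      tib <- rbind(P_c + 20 * m_t, P_c - 20 * m_t,
                   P_c + 6 * m_t, P_c - 6 * m_t,
                   t(apply(poutl, 1, function(ab) P_c + ab[1] * m_t + ab[2] * d_T)))
      out$knee_native <- rbind(fem, tib)
    }
    out
  })
}

# structure masks (logical matrices, disjoint across structures: implant
# takes precedence over bone where they overlap)
leg_masks <- function(geo, implant, dim) {
  grid <- pixel_grid(dim)
  w <- with(geo, {
    shaft_len <- vnorm(K - J) - 4
    femur <- raster_disc(grid, H, 16) |
      raster_capsule(grid, H, J, 6) |
      raster_disc(grid, J, 8) |
      raster_disc(grid, J + 18 * d_S + c(sgn * 8, 0), 5) |
      raster_capsule(grid, J, J + shaft_len * d_S, 8) |
      raster_rect(grid, C_f, l_f, -d_F, 24, 18)
    # distal normal of the ankle joint line: the talar dome's flat superior
    # edge runs along the ankle line so that the obliquity is observable
    n_a <- perp2(a_l); if (sum(n_a * d_T) < 0) n_a <- -n_a
    tibia <- raster_rect(grid, P_c, m_t, d_T, 24, 14) |
      raster_capsule(grid, P_c + 8 * d_T, A - 16 * d_T, 7) |
      raster_rect(grid, A - 5 * n_a, a_l, -n_a, 10, 14)
    fibula <- raster_capsule(grid, P_c + 24 * d_T + 14 * lat_T,
                             A - 22 * d_T + 12 * lat_T, 3)
    talus <- raster_dome(grid, A + 2 * n_a, 14, A, n_a)
    masks <- list(femur = femur, tibia = tibia, fibula = fibula, talus = talus)
    if (implant == "tka") {
      imp_f <- raster_rect(grid, C_f, l_f, -d_F, 22, 12)
      imp_t <- raster_rect(grid, P_c, m_t, d_T, 22, 5) |
        raster_capsule(grid, P_c + 5 * d_T, P_c + 55 * d_T, 4)
      masks$femur <- masks$femur & !imp_f & !imp_t
      masks$tibia <- masks$tibia & !imp_f & !imp_t
      masks$implant_femoral <- imp_f
      masks$implant_tibial <- imp_t
    }
    masks
  })
  w
}

build_leg_truth <- function(spec, hip_center, side) {
  geo <- leg_geometry(spec, hip_center, side)
  dim <- spec$image_size
  pts <- leg_landmarks(geo, spec$implant)
  masks <- leg_masks(geo, spec$implant, dim)

  # geometry-fit check: nothing may touch the image border
  border_hit <- vapply(masks, function(m) {
    any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)])
  }, logical(1))
  all_xy <- do.call(rbind, pts)
  inside <- all(all_xy[, 1] >= 0 & all_xy[, 1] <= dim[2] - 1 &
                  all_xy[, 2] >= 0 & all_xy[, 2] <= dim[1] - 1)
  if (any(border_hit) || !inside) {
    stop("phantom geometry does not fit in the image frame; ",
         "enlarge image_size or shorten the leg", call. = FALSE)
  }

  lms <- lapply(names(pts), function(region) {
    schema <- landmark_schema(region)
    landmark_set(region, data.frame(
      name = schema$name, role = schema$role,
      x = pts[[region]][, 1], y = pts[[region]][, 2],
      confidence = 1), frame = "image")
  })
  names(lms) <- names(pts)

  structure(list(
    side = side,
    landmarks = lms,
    masks = masks,
    true_angles = ground_truth_angles(spec),
    shaft_line = list(point = geo$J, direction = geo$d_S),
    centers = list(hip = geo$H, knee_femoral = geo$C_f,
                   knee_tibial = geo$P_c, ankle = geo$A),
    implant = spec$implant
  ), class = "leg_ground_truth")
}

#' Generate a synthetic full-leg radiograph with ground truth
#'
#' Renders the leg(s) described by `spec` as brighter-than-background filled
#' primitives (background 0.1, bone 0.6, implant 0.95 on a \[0, 1\] scale),
#' applies Gaussian blur and seeded additive Gaussian noise, and returns the
#' image together with exact per-leg ground truth: landmark sets, structure
#' masks, the anatomical shaft axis, and the closed-form alignment angles.
#'
#' @param spec a [phantom_spec()]. With `bilateral = TRUE` two mirrored legs
#'   are rendered in one frame.
#' @return an object of class `leg_phantom`: a list with elements
#'   `radiograph` (a [radiograph()]) and `legs` (list of one or two
#'   `leg_ground_truth` objects).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' ph$legs[[1]]$true_angles
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  dim <- spec$image_size
  legs <- list(build_leg_truth(spec, spec$hip_center, spec$side))
  if (spec$bilateral) {
    m <- mirror_phantom_spec(spec)
    legs <- c(legs, list(build_leg_truth(m, m$hip_center, m$side)))
  }

  img <- matrix(0.1, dim[1], dim[2])
  for (leg in legs) {
    for (lab in names(leg$masks)) {
      val <- if (startsWith(lab, "implant")) 0.95 else 0.6
      img[leg$masks[[lab]]] <- val
    }
  }
  img <- gauss_blur(img, spec$blur_sigma)
  set.seed(spec$seed)
  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                        nrow(img), ncol(img))
  }
  img <- clamp(img, 0, 1)

  structure(list(
    radiograph = radiograph(img, window_center = 0.5, window_width = 1,
                            source_id = sprintf("phantom_seed%d", spec$seed)),
    legs = legs,
    spec = spec
  ), class = "leg_phantom")
}

#' @export
print.leg_phantom <- function(x, ...) {
  cat(sprintf("<leg_phantom> %dx%d px, %d leg(s), implant=%s, seed=%d\n",
              x$spec$image_size[1], x$spec$image_size[2], length(x$legs),
              x$spec$implant, x$spec$seed))
  for (leg in x$legs) {
    cat(sprintf("  %-5s: %s\n", leg$side,
                paste(sprintf("%s=%.1f", names(leg$true_angles),
                              leg$true_angles), collapse = " ")))
  }
  invisible(x)
}

## ---- spec sampling ---------------------------------------------------------

default_phantom_ranges <- function() {
  list(
    knee_varus_valgus = c(-8, 8),
    femoral_jointline_obliquity = c(-4, 4),
    plateau_obliquity = c(-4, 4),
    ankle_obliquity = c(-4, 4),
    anat_mech_femur_angle = c(5, 7),
    femur_length = c(185, 215),
    tibia_length = c(165, 195)
  )
}

#' Sample random phantom specifications
#'
#' Draws `n` phantom specs with each varied field uniform within its range.
#' The default ranges emulate a TKA-referral population: varus/valgus within
#' +/-8 degrees, joint-line obliquities within +/-4 degrees, an
#' anatomical-mechanical femoral angle of 5-7 degrees, and segment lengths
#' varying by about +/-8%.
#'
#' @param n number of specs (>= 1).
#' @param ranges named list of `c(lo, hi)` intervals overriding the
#'   defaults; fields not listed keep their fixed default value.
#' @param seed integer seed; the i-th spec receives rendering seed
#'   `seed * 1000 + i`.
#' @param side `"right"`, `"left"` or `"random"`.
#' @param implant `"none"`, `"tka"` or `"random"`.
#' @param bilateral render bilateral phantoms.
#' @return list of [phantom_spec()] objects.
#' @export
sample_phantom_specs <- function(n, ranges = list(), seed = 1L,
                                 side = "random", implant = "none",
                                 bilateral = FALSE) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  rng <- utils::modifyList(default_phantom_ranges(), ranges)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2]) {
      stop(sprintf("invalid range for '%s': must be c(lo, hi) with lo <= hi", nm),
           call. = FALSE)
    }
  }
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    draw <- function(nm) stats::runif(1, rng[[nm]][1], rng[[nm]][2])
    sd_i <- if (side == "random") sample(c("left", "right"), 1) else side
    imp_i <- if (implant == "random") sample(c("none", "tka"), 1) else implant
    phantom_spec(
      side = sd_i,
      knee_varus_valgus = draw("knee_varus_valgus"),
      femoral_jointline_obliquity = draw("femoral_jointline_obliquity"),
      plateau_obliquity = draw("plateau_obliquity"),
      ankle_obliquity = draw("ankle_obliquity"),
      anat_mech_femur_angle = draw("anat_mech_femur_angle"),
      femur_length = draw("femur_length"),
      tibia_length = draw("tibia_length"),
      implant = imp_i,
      bilateral = bilateral,
      seed = as.integer(seed) * 1000L + i
    )
  })
}
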
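test_that("back-projection applies offset, scale and flip as documented", {
  tf <- list(offset = c(100, 50), flip = FALSE, crop_size = c(512, 512),
             out_size = c(256L, 256L))  # scales (2, 2)
  lms <- landmark_set("talus", data.frame(
    name = c("tal_med", "tal_lat"), role = c("talus_medial", "talus_lateral"),
    x = c(10, 0), y = c(10, 0), confidence = 1), frame = "crop")
  out <- project_to_image(lms, tf)
  expect_equal(c(out$x[1], out$y[1]), c(120, 70))

  tf2 <- list(offset = c(0, 0), flip = TRUE, crop_size = c(256, 256),
              out_size = c(256L, 256L))
  out2 <- project_to_image(lms, tf2)
  expect_equal(c(out2$x[1], out2$y[1]), c(245, 10))

  expect_error(project_to_image(out, tf), "crop-frame")
})

test_that("the Kasa circle fit is exact on circles and rejects degeneracy", {
  fit <- fit_circle(rbind(c(0, 1), c(1, 0), c(0, -1)))
  expect_equal(fit$center, c(0, 0), tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)

  set.seed(8)
  th <- seq(0.2, 5.8, length.out = 5)
  pts <- cbind(3 + 2 * cos(th), 4 + 2 * sin(th)) +
    matrix(runif(10, -0.01, 0.01), 5, 2)
  fit2 <- fit_circle(pts)
  # independent oracle: coarse grid search minimizing radial residual
  grid <- expand.grid(cx = seq(2.8, 3.2, by = 0.01), cy = seq(3.8, 4.2, by = 0.01))
  resid <- vapply(seq_len(nrow(grid)), function(i) {
    d <- sqrt((pts[, 1] - grid$cx[i])^2 + (pts[, 2] - grid$cy[i])^2)
    sum((d - mean(d))^2)
  }, numeric(1))
  oracle <- unlist(grid[which.min(resid), ])
  expect_lt(sqrt(sum((fit2$center - oracle)^2)), 0.05)
  expect_lt(sqrt(sum((fit2$center - c(3, 4))^2)), 0.05)

  expect_error(fit_circle(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
  expect_error(fit_circle(rbind(c(0, 0), c(1, 1))), "3 points")
})

test_that("the shaft axis fit recovers rectangle orientations within 0.1 degree", {
  vert <- matrix(FALSE, 300, 100)
  vert[30:270, 40:60] <- TRUE
  ax <- fit_shaft_axis(vert)
  expect_equal(ax$direction, c(0, 1), tolerance = 1e-9)

  # analytic rotated rectangle: points within the rotated slab
  g <- limbalign:::pixel_grid(c(300, 160))
  th <- limbalign:::deg2rad(7)
  u <- c(sin(th), cos(th))   # axis direction, 7 deg from vertical
  ctr <- c(80, 150)
  dx <- g$x - ctr[1]; dy <- g$y - ctr[2]
  along <- dx * u[1] + dy * u[2]
  across <- -dx * u[2] + dy * u[1]
  rect <- abs(along) <= 120 & abs(across) <= 10
  ax7 <- fit_shaft_axis(rect)
  ang <- limbalign:::rad2deg(acos(min(1, abs(sum(ax7$direction * u)))))
  expect_lt(ang, 0.1)

  thin <- matrix(FALSE, 40, 40)
  thin[10:19, 15:25] <- TRUE
  expect_error(fit_shaft_axis(thin), "50 rows")
})

test_that("angular primitives agree with a dot/cross-product oracle", {
  expect_equal(signed_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(signed_angle(c(1, 0), c(-1, 0)), 180)
  expect_equal(varus_deviation(c(0, 1), c(sin(pi / 60), cos(pi / 60)), "right"),
               3, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:200) {
    a <- limbalign:::unitv(rnorm(2)); b <- limbalign:::unitv(rnorm(2))
    oracle <- limbalign:::rad2deg(atan2(a[1] * b[2] - a[2] * b[1], sum(a * b)))
    expect_equal(limbalign:::rot_angle(a, b), oracle, tolerance = 1e-9)
    expect_equal(signed_angle(a, b), abs(oracle), tolerance = 1e-9)
  }
})

test_that("axes construction produces the documented centres and handles gaps", {
  ph <- neutral_phantom(17)
  leg <- ph$legs[[1]]
  axes <- build_axes(leg$landmarks, femur_mask = leg$masks$femur,
                     side = leg$side, shaft_line = leg$shaft_line)
  expect_equal(axes$head_center, leg$centers$hip, tolerance = 1e-9)
  expect_equal(axes$ankle_center, leg$centers$ankle, tolerance = 1e-9)
  # neutral phantom: femoral and tibial mechanical axes collinear
  expect_lt(signed_angle(axes$mech_femur$direction, axes$mech_tibia$direction),
            1e-6)

  # talus midpoint example
  lms <- landmark_set("talus", data.frame(
    name = c("tal_med", "tal_lat"), role = c("talus_medial", "talus_lateral"),
    x = c(10, 50), y = c(800, 800), confidence = 1), frame = "image")
  ax2 <- build_axes(list(talus = lms), side = "right")
  expect_equal(ax2$ankle_center, c(30, 800))

  # removing the tibial spines marks the tibial mechanical axis unavailable
  broken <- leg$landmarks
  broken$knee_native$confidence[broken$knee_native$role %in%
    c("tibial_spine_medial", "tibial_spine_lateral")] <- 0
  ax3 <- build_axes(broken, side = leg$side, shaft_line = leg$shaft_line)
  expect_true(limbalign:::is_unavailable(ax3$mech_tibia))
})

test_that("oracle-path measurement recovers the generating angles to 1e-6 degree", {
  specs <- sample_phantom_specs(20, seed = 301, implant = "random")
  for (sp in specs) {
    ph <- generate_phantom(sp)
    got <- oracle_angles(ph)
    expect_lt(max(abs(got - ph$legs[[1]]$true_angles)), 1e-6)
  }
})

test_that("angles are invariant to rotation, scale and mirroring of the inputs", {
  ph <- generate_phantom(phantom_spec(knee_varus_valgus = 6,
                                      plateau_obliquity = 3,
                                      ankle_obliquity = -2, seed = 23))
  leg <- ph$legs[[1]]
  base <- compute_alignment(build_axes(leg$landmarks, side = leg$side,
                                       shaft_line = leg$shaft_line))
  bangles <- limbalign:::report_angles(base)

  rotate_lms <- function(lms, R, ctr) {
    out <- lms
    p <- R %*% (rbind(lms$x, lms$y) - ctr) + ctr
    out$x <- p[1, ]; out$y <- p[2, ]
    out
  }
  for (ang in c(13.7, -41, 90)) {
    R <- limbalign:::rot2(ang)
    ctr <- c(130, 250)
    rl <- lapply(leg$landmarks, rotate_lms, R = R, ctr = ctr)
    rsl <- list(point = as.vector(R %*% (leg$shaft_line$point - ctr) + ctr),
                direction = as.vector(R %*% leg$shaft_line$direction))
    got <- limbalign:::report_angles(
      compute_alignment(build_axes(rl, side = leg$side, shaft_line = rsl)))
    expect_lt(max(abs(got - bangles)), 1e-6)
  }

  # uniform scaling
  scale_lms <- function(lms, s) { out <- lms; out$x <- s * lms$x; out$y <- s * lms$y; out }
  sl <- lapply(leg$landmarks, scale_lms, s = 3.7)
  ssl <- list(point = 3.7 * leg$shaft_line$point, direction = leg$shaft_line$direction)
  got_s <- limbalign:::report_angles(
    compute_alignment(build_axes(sl, side = leg$side, shaft_line = ssl)))
  expect_lt(max(abs(got_s - bangles)), 1e-6)

  # mirroring with side toggle (mirrored phantom render)
  mir <- phantom_spec(knee_varus_valgus = 6, plateau_obliquity = 3,
                      ankle_obliquity = -2, seed = 23)
  mir$side <- "left"
  mir$hip_center[1] <- (mir$image_size[2] - 1) - mir$hip_center[1]
  mleg <- generate_phantom(mir)$legs[[1]]
  got_m <- limbalign:::report_angles(
    compute_alignment(build_axes(mleg$landmarks, side = "left",
                                 shaft_line = mleg$shaft_line)))
  expect_lt(max(abs(got_m - bangles)), 1e-9)
})

test_that("mask-based shaft fitting recovers FSAmTA within rasterization accuracy", {
  specs <- sample_phantom_specs(6, seed = 401)
  for (sp in specs) {
    leg <- generate_phantom(sp)$legs[[1]]
    axes <- build_axes(leg$landmarks, femur_mask = leg$masks$femur,
                       side = leg$side, shaft_line = NULL)
    rep <- compute_alignment(axes)
    expect_lt(abs(rep$angles$FSAmTA - leg$true_angles[["FSAmTA"]]), 0.2)
  }
})

test_that("detection rates count per-parameter availability", {
  mk_report <- function(avail) {
    ang <- lapply(stats::setNames(ANGLE_NAMES <- c("mMPTA", "mLDFA", "mFAmTA",
                                                   "mLDTA", "FSAmTA"),
                                  ANGLE_NAMES), function(nm) {
      if (nm %in% avail) 90 else limbalign:::unavailable("missing")
    })
    structure(list(side = "right", angles = ang, intermediate = NULL),
              class = "alignment_report")
  }
  reports <- c(replicate(9, mk_report(c("mMPTA", "mLDFA", "mFAmTA", "mLDTA",
                                        "FSAmTA")), simplify = FALSE),
               list(mk_report(c("mMPTA", "mLDFA", "mFAmTA", "FSAmTA"))))
  rates <- detection_rates(reports)
  expect_equal(rates$percent[rates$parameter == "mLDTA"], 90)
  expect_equal(rates$percent[rates$parameter == "mMPTA"], 100)
  expect_error(detection_rates(list()), "no reports")
})
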
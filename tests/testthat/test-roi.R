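fake_result <- function(label, x0, y0, x1, y1) {
  structure(list(label = label, box = box_make(x0, y0, x1, y1),
                 mask = NULL, score = 1), class = "segmentation_result")
}

test_that("leg splitting clusters separated x-centres into two groups of four", {
  mk <- function(cx) lapply(c("femur", "tibia", "fibula", "talus"), function(l) {
    fake_result(l, cx - 40, 0, cx + 40, 100)
  })
  res <- c(mk(180), mk(620))
  groups <- split_legs(res)
  expect_length(groups, 2)
  expect_length(groups[[1]]$structures, 4)
  expect_length(groups[[2]]$structures, 4)

  expect_length(split_legs(mk(180)), 1)

  dup <- list(fake_result("femur", 100, 0, 140, 50),
              fake_result("femur", 100, 0, 140, 50))
  expect_error(split_legs(dup), "grouping error")
})

test_that("the fibula/tibia relation determines the leg side", {
  expect_equal(determine_leg_side(box_make(120, 0, 160, 10), box_make(90, 0, 110, 10)),
               "right")
  expect_equal(determine_leg_side(box_make(640, 0, 680, 10), box_make(690, 0, 710, 10)),
               "left")
  expect_error(determine_leg_side(box_make(90, 0, 110, 10), box_make(90, 0, 110, 10)),
               "undetermined")
  # a non-standard display orientation inverts the rule
  expect_equal(determine_leg_side(box_make(120, 0, 160, 10), box_make(90, 0, 110, 10),
                                  standard_display = FALSE), "left")
})

test_that("region crops follow the quarter/eighth box fractions", {
  img <- matrix(0.2, 1000, 800)
  leg <- structure(list(structures = list(
    femur = fake_result("femur", 300, 100, 420, 500),
    tibia = fake_result("tibia", 310, 480, 410, 900)
  ), side = "right"), class = "leg_group")

  pf <- crop_region("proximal_femur", leg, img)
  # upper quarter: y in [100, 200) before padding; padding is max(5%, 8) px
  expect_equal(pf$transform$offset[2], floor(100 - max(0.05 * 100, 8)))
  expect_lte(pf$transform$offset[2] + pf$transform$crop_size[1], ceiling(200 + 8) + 8)

  kn <- crop_region("knee_native", leg, img)
  # lower eighth of femur [450, 500) united with upper eighth of tibia [480, 532.5)
  pad <- max(0.05 * (532.5 - 450), 8)
  expect_equal(kn$transform$offset[2], floor(450 - pad))
  expect_equal(kn$transform$offset[2] + kn$transform$crop_size[1],
               ceiling(532.5 + pad))

  # missing talus produces a region-unavailable signal
  out <- crop_region("talus", leg, img)
  expect_s3_class(out, "region_unavailable")
  expect_equal(out$reason, "missing_talus")
})

test_that("prepared inputs are 256x256, flip only left legs, and survive constant crops", {
  img <- matrix(runif(500 * 400), 500, 400)
  leg_r <- structure(list(structures = list(
    talus = fake_result("talus", 100, 380, 150, 420)), side = "right"),
    class = "leg_group")
  leg_l <- leg_r; leg_l$side <- "left"

  pr <- prepare_model_input(crop_region("talus", leg_r, img))
  pl <- prepare_model_input(crop_region("talus", leg_l, img))
  expect_equal(dim(pr$pixels), c(256, 256))
  expect_false(pr$transform$flip)
  expect_true(pl$transform$flip)

  const <- prepare_model_input(structure(list(
    region = "talus", pixels = matrix(0.4, 30, 30),
    transform = list(offset = c(0, 0), flip = FALSE, crop_size = c(30, 30),
                     out_size = NULL),
    side = "right"), class = "region_crop"))
  expect_true(all(is.finite(const$pixels)))
  expect_equal(diff(range(const$pixels)), 0)
})

test_that("the crop transform round-trips points within 1e-9", {
  tf <- list(offset = c(137, 52), flip = TRUE, crop_size = c(61, 83),
             out_size = c(256L, 256L))
  set.seed(1)
  pts <- cbind(runif(1000, 0, 255), runif(1000, 0, 255))
  img_pts <- limbalign:::transform_crop_to_image(pts, tf)
  back <- limbalign:::transform_image_to_crop(img_pts, tf)
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("mirroring the image yields pixel-identical model inputs", {
  spec <- phantom_spec(knee_varus_valgus = 4, seed = 21)
  mir <- spec
  mir$side <- "left"
  mir$hip_center[1] <- (spec$image_size[2] - 1) - spec$hip_center[1]
  prep <- function(sp) {
    ph <- generate_phantom(sp)
    img <- normalized_pixels(ph$radiograph)
    g <- assign_leg_sides(split_legs(oracle_segment(ph)))[[1]]
    prepare_model_input(crop_region("knee_native", g, img))$pixels
  }
  # mirrored-phantom pixels differ only in the seeded noise field; compare
  # noise-free renders for exact pixel identity
  spec$noise_sd <- 0; mir$noise_sd <- 0
  expect_identical(prep(spec), prep(mir))
})
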
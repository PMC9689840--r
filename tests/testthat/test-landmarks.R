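test_that("landmark schemas carry the fixed counts and roles", {
  pf <- landmark_schema("proximal_femur")
  expect_equal(nrow(pf), 9)
  expect_equal(sum(pf$role == "head_contour"), 5)
  kn <- landmark_schema("knee_native")
  expect_equal(nrow(kn), 20)
  expect_equal(sum(kn$part == "femoral"), 10)
  expect_equal(sum(kn$part == "tibial"), 10)
  tk <- landmark_schema("knee_tka")
  expect_equal(nrow(tk), 15)
  expect_equal(sum(tk$part == "femoral"), 5)
  expect_equal(sum(tk$part == "tibial"), 10)
  expect_equal(nrow(landmark_schema("talus")), 2)
  expect_error(landmark_schema("patella"))
})

test_that("landmark sets must match their schema", {
  bad <- data.frame(name = c("a", "b", "c"), role = "x", x = 1, y = 1,
                    confidence = 1)
  expect_error(landmark_set("talus", bad), "schema")
})

test_that("heatmap decoding recovers delta and Gaussian peaks", {
  hm <- array(0, c(64, 64, 2))
  hm[21, 11, 1] <- 1      # (x=10, y=20)
  g <- expand.grid(y = 0:63, x = 0:63)
  hm[, , 2] <- matrix(exp(-((g$x - 30.5)^2 + (g$y - 40.5)^2) / (2 * 2^2)), 64, 64)
  out <- decode_heatmaps(hm, "talus", peak_threshold = 0.2)
  expect_equal(c(out$x[1], out$y[1]), c(10, 20))
  expect_equal(out$confidence[1], 1.0)
  # independent oracle: centre of mass over the full array
  w <- hm[, , 2]
  com <- c(sum(w * matrix(g$x, 64, 64)) / sum(w),
           sum(w * matrix(g$y, 64, 64)) / sum(w))
  expect_lt(sqrt(sum((c(out$x[2], out$y[2]) - com)^2)), 0.25)
})

test_that("all-zero channels are flagged missing and shapes are checked", {
  hm <- array(0, c(32, 32, 2))
  hm[5, 5, 1] <- 1
  out <- decode_heatmaps(hm, "talus")
  expect_false(is.na(out$x[1]))
  expect_true(is.na(out$x[2]))
  expect_equal(out$confidence[2], 0)
  expect_error(decode_heatmaps(array(0, c(32, 32, 3)), "talus"), "channels")
})

test_that("decoding is equivariant to integer translations of the heatmaps", {
  set.seed(4)
  g <- expand.grid(y = 0:63, x = 0:63)
  base <- array(0, c(64, 64, 2))
  base[, , 1] <- matrix(exp(-((g$x - 20)^2 + (g$y - 25)^2) / 8), 64, 64)
  base[, , 2] <- matrix(exp(-((g$x - 40)^2 + (g$y - 30)^2) / 8), 64, 64)
  shifted <- array(0, c(64, 64, 2))
  shifted[6:64, 4:64, ] <- base[1:59, 1:61, ]   # shift by (dx=3, dy=5)
  a <- decode_heatmaps(base, "talus")
  b <- decode_heatmaps(shifted, "talus")
  expect_equal(b$x, a$x + 3, tolerance = 1e-9)
  expect_equal(b$y, a$y + 5, tolerance = 1e-9)
})

test_that("augmentation co-transforms crops and landmark coordinates", {
  ph <- neutral_phantom(31)
  img <- normalized_pixels(ph$radiograph)
  g <- assign_leg_sides(split_legs(oracle_segment(ph)))[[1]]
  crop <- prepare_model_input(crop_region("knee_native", g, img))
  lms <- oracle_landmarks(ph$legs[[1]], "knee_native", crop$transform)
  aug <- limbalign:::augment_crop(crop$pixels, cbind(lms$x, lms$y), 10, 1)
  # decoding the targets built from the transformed coordinates must return
  # those coordinates (0.5 px at the 128-grid resolution)
  Y <- limbalign:::heatmap_targets(aug$xy, 4)
  hm <- array(Y, c(128, 128, nrow(aug$xy)))
  dec <- decode_heatmaps(hm, "knee_native", peak_threshold = 0, scale = 2)
  inside <- aug$xy[, 1] > 8 & aug$xy[, 1] < 248 & aug$xy[, 2] > 8 & aug$xy[, 2] < 248
  err <- sqrt((dec$x - aug$xy[, 1])^2 + (dec$y - aug$xy[, 2])^2)
  expect_lt(max(err[inside]), 0.5)
})

test_that("landmark training is schema-checked, seeded and loss-decreasing", {
  ts <- phantom_training_crops("talus", 6, seed = 50)
  wrong <- phantom_training_crops("proximal_femur", 2, seed = 51)
  expect_error(train_landmark_model("talus", wrong$crops, wrong$landmarks),
               "schema")
  a <- train_landmark_model("talus", ts$crops, ts$landmarks,
                            lm_config(epochs = 5, seed = 0))
  b <- train_landmark_model("talus", ts$crops, ts$landmarks,
                            lm_config(epochs = 5, seed = 0))
  expect_identical(a$loss_history, b$loss_history)
  expect_lt(tail(a$loss_history, 1), a$loss_initial)
})

test_that("the oracle landmark placer inverts the crop transform exactly", {
  ph <- generate_phantom(phantom_spec(side = "left", seed = 13))
  img <- normalized_pixels(ph$radiograph)
  g <- assign_leg_sides(split_legs(oracle_segment(ph)))[[1]]
  crop <- prepare_model_input(crop_region("talus", g, img))
  expect_true(crop$transform$flip)
  lms <- oracle_landmarks(ph$legs[[1]], "talus", crop$transform)
  expect_equal(nrow(lms), 2)
  back <- project_to_image(lms, crop$transform)
  truth <- ph$legs[[1]]$landmarks$talus
  expect_lt(max(abs(back$x - truth$x), abs(back$y - truth$y)), 1e-9)
})

test_that("trained talus placement stays within 3 px at 256x256 on held-out crops", {
  models <- cached_models()
  hs <- phantom_training_crops("talus", 10, seed = 600)
  errs <- unlist(lapply(seq_along(hs$crops), function(i) {
    det <- detect_landmarks(hs$crops[[i]], models$talus)
    truth <- hs$landmarks[[i]]
    sqrt((det$x - truth$x)^2 + (det$y - truth$y)^2)
  }))
  expect_lte(mean(errs), 3)
})

test_that("held-out landmark error does not degrade when training doubles", {
  errs_at <- function(n, seed) {
    ts <- phantom_training_crops("talus", n, seed = seed)
    m <- train_landmark_model("talus", ts$crops, ts$landmarks,
                              lm_config(epochs = 30, seed = 0))
    hs <- phantom_training_crops("talus", 6, seed = seed + 7000)
    mean(unlist(lapply(seq_along(hs$crops), function(i) {
      det <- detect_landmarks(hs$crops[[i]], m)
      truth <- hs$landmarks[[i]]
      sqrt((det$x - truth$x)^2 + (det$y - truth$y)^2)
    })))
  }
  deltas <- vapply(c(1001, 1002, 1003), function(s) {
    errs_at(40, s) - errs_at(20, s)
  }, numeric(1))
  # decreasing or statistically flat
  expect_lte(mean(deltas), 0.5)
})
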
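test_that("training set labels outside the vocabulary are rejected", {
  tr <- phantom_training_images(2, seed = 1)
  bad <- tr$masks
  names(bad[[1]])[1] <- "patella"
  expect_error(train_segmenter(tr$images, bad), "patella")
  expect_error(train_segmenter(tr$images[1], tr$masks[1]), "at least 2")
})

test_that("exactly floor(n/2) training images are flip-augmented", {
  tr <- phantom_training_images(6, seed = 2)
  # tiny run: bookkeeping only
  m6 <- train_segmenter(tr$images, tr$masks, seg_config(epochs = 2, seed = 0))
  expect_equal(m6$n_flipped, 3L)
  expect_length(m6$flip_idx, 3L)
  tr10 <- phantom_training_images(10, seed = 2)
  m10 <- train_segmenter(tr10$images, tr10$masks, seg_config(epochs = 1, seed = 0))
  expect_equal(m10$n_flipped, 5L)
})

test_that("training is seeded-deterministic and the loss decreases", {
  tr <- phantom_training_images(8, seed = 3)
  a <- train_segmenter(tr$images, tr$masks, seg_config(epochs = 5, seed = 0))
  b <- train_segmenter(tr$images, tr$masks, seg_config(epochs = 5, seed = 0))
  expect_identical(a$loss_history, b$loss_history)
  expect_identical(a$W, b$W)
  expect_lt(tail(a$loss_history, 1), a$loss_history[1])
  expect_lt(tail(a$loss_history, 1), a$loss_initial)
})

test_that("the ground-truth oracle yields one tight-boxed result per structure", {
  ph <- neutral_phantom()
  res <- oracle_segment(ph)
  expect_length(res, 4)
  expect_setequal(vapply(res, `[[`, "", "label"),
                  c("femur", "tibia", "fibula", "talus"))
  for (r in res) {
    expect_equal(r$score, 1.0)
    idx <- which(r$mask, arr.ind = TRUE)
    expect_equal(unname(r$box),
                 c(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1])))
  }
  tka <- generate_phantom(phantom_spec(implant = "tka", seed = 5))
  expect_length(oracle_segment(tka), 6)
  expect_true(all(c("implant_femoral", "implant_tibial") %in%
                    vapply(oracle_segment(tka), `[[`, "", "label")))
})

test_that("a blank image segments to an empty list", {
  models <- cached_models()
  expect_length(segment(matrix(0.1, 512, 260), models$segmenter), 0)
})

test_that("segmentation is side-insensitive: flip in, flip out, IoU >= 0.99", {
  models <- cached_models()
  img <- normalized_pixels(generate_phantom(phantom_spec(seed = 77))$radiograph)
  res <- segment(img, models$segmenter)
  resf <- segment(flip_h_matrix(img), models$segmenter)
  expect_equal(sort(vapply(res, `[[`, "", "label")),
               sort(vapply(resf, `[[`, "", "label")))
  for (r in res) {
    match <- Filter(function(q) q$label == r$label, resf)[[1]]
    back <- flip_h_matrix(match$mask)
    expect_gte(mask_iou(r$mask, back), 0.99)
  }
})

test_that("held-out phantom bones are recovered with mask IoU >= 0.6", {
  models <- cached_models()
  te <- phantom_training_images(6, seed = 200)
  for (i in seq_along(te$images)) {
    res <- segment(te$images[[i]], models$segmenter)
    truth <- te$phantoms[[i]]$legs[[1]]$masks
    for (lab in c("femur", "tibia", "fibula", "talus")) {
      cand <- Filter(function(r) r$label == lab, res)
      expect_gt(length(cand), 0, label = sprintf("%s detected", lab))
      iou <- max(vapply(cand, function(r) mask_iou(r$mask, truth[[lab]]), 0))
      expect_gte(iou, 0.6)
    }
  }
})

test_that("model checkpoints round-trip through a single file", {
  tr <- phantom_training_images(2, seed = 4)
  m <- train_segmenter(tr$images, tr$masks, seg_config(epochs = 1, seed = 0))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  expect_identical(load_model(path)$W, m$W)
})
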
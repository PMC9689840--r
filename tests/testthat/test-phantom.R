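test_that("closed-form ground-truth angles follow the generating parameters", {
  neutral <- phantom_spec()
  expect_equal(unname(ground_truth_angles(neutral)),
               c(90, 90, 180, 90, 174))
  expect_equal(ground_truth_angles(phantom_spec(knee_varus_valgus = 3))[["mFAmTA"]],
               177)
  expect_equal(ground_truth_angles(phantom_spec(plateau_obliquity = 3))[["mMPTA"]],
               87)
  expect_equal(ground_truth_angles(phantom_spec(anat_mech_femur_angle = 6))[["FSAmTA"]],
               174)
  expect_equal(ground_truth_angles(phantom_spec(femoral_jointline_obliquity = -2))[["mLDFA"]],
               88)
  expect_equal(ground_truth_angles(phantom_spec(ankle_obliquity = 4))[["mLDTA"]],
               94)
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(femur_length = -5), "positive")
  expect_error(phantom_spec(plateau_obliquity = 20), "15")
  expect_error(phantom_spec(image_size = c(10, 10)), "image_size")
})

test_that("rendering is seeded and bit-identical on repeat", {
  a <- generate_phantom(phantom_spec(seed = 42))
  b <- generate_phantom(phantom_spec(seed = 42))
  expect_identical(a$radiograph$pixels, b$radiograph$pixels)
  expect_identical(a$legs[[1]]$landmarks, b$legs[[1]]$landmarks)
  c <- generate_phantom(phantom_spec(seed = 43))
  expect_false(identical(a$radiograph$pixels, c$radiograph$pixels))
})

test_that("mirrored specs mirror landmarks about the vertical midline and keep angles", {
  spec <- phantom_spec(knee_varus_valgus = 5, plateau_obliquity = 2, seed = 7)
  mir <- spec
  mir$side <- "left"
  mir$hip_center[1] <- (spec$image_size[2] - 1) - spec$hip_center[1]
  a <- generate_phantom(spec)$legs[[1]]
  b <- generate_phantom(mir)$legs[[1]]
  W <- spec$image_size[2]
  for (region in names(a$landmarks)) {
    expect_equal(b$landmarks[[region]]$x, (W - 1) - a$landmarks[[region]]$x,
                 tolerance = 1e-9)
    expect_equal(b$landmarks[[region]]$y, a$landmarks[[region]]$y,
                 tolerance = 1e-9)
  }
  expect_equal(a$true_angles, b$true_angles)
})

test_that("rendering is translation-equivariant in the hip centre", {
  base <- phantom_spec(seed = 11)
  shifted <- base
  shifted$hip_center <- base$hip_center + c(7, -9)
  a <- generate_phantom(base)$legs[[1]]
  b <- generate_phantom(shifted)$legs[[1]]
  for (region in names(a$landmarks)) {
    expect_equal(b$landmarks[[region]]$x, a$landmarks[[region]]$x + 7,
                 tolerance = 1e-9)
    expect_equal(b$landmarks[[region]]$y, a$landmarks[[region]]$y - 9,
                 tolerance = 1e-9)
  }
  expect_equal(a$true_angles, b$true_angles)
})

test_that("every ground-truth landmark lies in its structure mask dilated by 2 px", {
  specs <- sample_phantom_specs(4, seed = 77, implant = "random")
  region_mask <- function(leg, region) {
    switch(region,
      proximal_femur = leg$masks$femur,
      knee_native = leg$masks$femur | leg$masks$tibia,
      knee_tka = leg$masks$implant_femoral | leg$masks$implant_tibial,
      talus = leg$masks$talus)
  }
  for (sp in specs) {
    leg <- generate_phantom(sp)$legs[[1]]
    for (region in names(leg$landmarks)) {
      mask <- region_mask(leg, region)
      lm <- leg$landmarks[[region]]
      d2 <- vapply(seq_len(nrow(lm)), function(k) {
        idx <- which(mask, arr.ind = TRUE)
        min((idx[, 2] - 1 - lm$x[k])^2 + (idx[, 1] - 1 - lm$y[k])^2)
      }, numeric(1))
      expect_true(all(sqrt(d2) <= 2 + 1e-9),
                  info = sprintf("region %s, max dist %.2f", region, max(sqrt(d2))))
    }
  }
})

test_that("bilateral rendering contains two disjoint leg mask groups", {
  ph <- generate_phantom(phantom_spec(bilateral = TRUE, seed = 9))
  expect_length(ph$legs, 2)
  union1 <- Reduce(`|`, ph$legs[[1]]$masks)
  union2 <- Reduce(`|`, ph$legs[[2]]$masks)
  expect_equal(sum(union1 & union2), 0)
  expect_setequal(vapply(ph$legs, `[[`, "", "side"), c("left", "right"))
})

test_that("a leg that does not fit the frame raises a geometry error", {
  expect_error(generate_phantom(phantom_spec(image_size = c(220, 100),
                                             femur_length = 300)),
               "fit")
})

test_that("spec sampling is seeded, range-bounded and validated", {
  a <- sample_phantom_specs(5, seed = 5)
  b <- sample_phantom_specs(5, seed = 5)
  expect_identical(a, b)
  many <- sample_phantom_specs(100, ranges = list(knee_varus_valgus = c(-8, 8)),
                               seed = 2)
  vv <- vapply(many, `[[`, 0, "knee_varus_valgus")
  expect_true(all(vv >= -8 & vv <= 8))
  expect_error(sample_phantom_specs(0), "positive")
  expect_error(sample_phantom_specs(3, ranges = list(knee_varus_valgus = c(5, -5))),
               "range")
})
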
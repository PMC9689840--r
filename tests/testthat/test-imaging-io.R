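test_that("window normalization maps centre to 0.5 and clips at the edges", {
  expect_equal(normalize_window(2048, 2048, 4096), 0.5)
  expect_equal(normalize_window(3072, 2048, 4096), 0.75)
  expect_equal(normalize_window(c(-100, 0), 2048, 4096), c(0, 0))
  expect_equal(normalize_window(c(4096, 9999), 2048, 4096), c(1, 1))
  expect_error(normalize_window(1, 0.5, 0), "positive")
})

test_that("window normalization is monotone and idempotent on normalized input", {
  v <- sort(runif(50, -1000, 6000))
  out <- normalize_window(v, 2048, 4096)
  expect_true(all(diff(out) >= 0))
  expect_equal(normalize_window(out, 0.5, 1), out)
})

test_that("PNG round trip applies full-range window defaults", {
  px <- matrix(runif(40 * 30), 40, 30)
  path <- tempfile(fileext = ".png")
  write_png_image(px, path)
  rg <- load_radiograph(path)
  expect_equal(rg$window_center, 127.5)
  expect_equal(rg$window_width, 255)
  expect_equal(dim(rg$pixels), c(40, 30))
  expect_equal(rg$pixels / 255, px, tolerance = 1 / 255)
})

test_that("minimal DICOM writes and reads back window tags and pixels", {
  px <- matrix(sample(0:4095, 32 * 20, replace = TRUE), 32, 20)
  path <- tempfile(fileext = ".dcm")
  write_dicom_minimal(px, path, window_center = 2048, window_width = 4096,
                      pixel_spacing = 0.143)
  rg <- load_radiograph(path)
  expect_equal(rg$window_center, 2048)
  expect_equal(rg$window_width, 4096)
  expect_equal(rg$pixel_spacing, c(0.143, 0.143))
  expect_identical(rg$pixels, px)
})

test_that("the DICOM writer is readable by an independent toolkit", {
  px <- matrix(sample(0:4095, 16 * 12, replace = TRUE), 16, 12)
  path <- tempfile(fileext = ".dcm")
  write_dicom_minimal(px, path, window_center = 1234, window_width = 2345)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import pydicom; d = pydicom.dcmread('", path, "'); ",
    "print(d.Rows, d.Columns, d.WindowCenter, d.WindowWidth, ",
    "int(d.pixel_array[3, 5]))"
  ))), stdout = TRUE, stderr = TRUE))
  vals <- as.numeric(tail(strsplit(paste(out, collapse = " "), " ")[[1]], 5))
  expect_equal(vals, c(16, 12, 1234, 2345, px[4, 6]))
})

test_that("loading failures raise distinct errors", {
  expect_error(load_radiograph(tempfile()), "not found")
  bad <- tempfile()
  writeBin(as.raw(1:64), bad)
  expect_error(load_radiograph(bad), "unreadable")
})
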
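test_that("ENVI and ascii round-trips preserve the image", {
  img <- tiny_image()
  tmp <- withr::local_tempdir()
  hdr <- file.path(tmp, "tiny.hdr")
  write_hyperspectral(img, hdr, "envi")
  back <- read_hyperspectral(hdr)
  # float32 storage: agreement to single precision
  expect_equal(back$values, img$values, tolerance = 1e-6)
  expect_equal(back$wavelengths, img$wavelengths)
  expect_equal(back$metadata$landcover, "vegetated")

  txt <- file.path(tmp, "tiny.txt")
  write_hyperspectral(img, txt, "ascii")
  back2 <- read_hyperspectral(txt)
  expect_equal(back2$values, img$values, tolerance = 1e-12)
  expect_equal(back2$metadata$scene_id, "tiny")
})

test_that("malformed files are refused rather than guessed", {
  tmp <- withr::local_tempdir()
  hdr <- file.path(tmp, "bad.hdr")
  write_hyperspectral(tiny_image(), hdr, "envi")
  lines <- readLines(hdr)
  writeLines(lines[!grepl("^wavelength =", lines)], hdr)
  expect_error(read_hyperspectral(hdr), "wavelength metadata missing")
  # non-monotone wavelength list
  writeLines(c(lines[!grepl("^wavelength =", lines)],
               sprintf("wavelength = { %s }",
                       paste(rev(seq(400, 720, 10)), collapse = ", "))), hdr)
  expect_error(read_hyperspectral(hdr), "increasing")
  expect_error(read_hyperspectral(file.path(tmp, "missing.hdr")), "not found")
})

test_that("wavelength resampling interpolates onto the 31-band grid", {
  wl_src <- seq(400, 1000, by = 20)
  set.seed(2)
  img <- spectral_image(array(runif(6 * 6 * length(wl_src)),
                              c(6, 6, length(wl_src))), wl_src)
  grid31 <- seq(400, 700, by = 10)
  out <- resample_wavelengths(img, grid31)
  expect_equal(dim(out)[3], 31)
  # identity grid: unchanged
  same <- resample_wavelengths(img, wl_src)
  expect_identical(same$values, img$values)
  # constant spectra stay constant
  cimg <- spectral_image(array(3, c(2, 2, length(wl_src))), wl_src)
  expect_true(all(resample_wavelengths(cimg, grid31)$values == 3))
  expect_error(resample_wavelengths(img, seq(300, 700, 10)), "extrapolation")
})

test_that("2x2 downsampling averages blocks and preserves the mean", {
  img <- tiny_image()
  out <- downsample_2x2(img)
  expect_equal(dim(out)[1:2], c(2, 3))
  # brute-force block-averaging oracle
  for (i in 1:2) for (j in 1:3) {
    block <- (img$values[2 * i - 1, 2 * j - 1, ] +
              img$values[2 * i, 2 * j - 1, ] +
              img$values[2 * i - 1, 2 * j, ] +
              img$values[2 * i, 2 * j, ]) / 4
    expect_equal(out$values[i, j, ], block)
  }
  # global mean spectrum preserved for even dims
  expect_equal(apply(out$values, 3, mean), apply(img$values, 3, mean))
  # odd trailing column dropped
  odd <- spectral_image(img$values[, 1:5, , drop = FALSE], img$wavelengths)
  expect_equal(dim(downsample_2x2(odd))[1:2], c(2, 2))
  # checkerboard of two spectra averages to their midpoint
  wl <- img$wavelengths
  a <- runif(33); b <- runif(33)
  cb <- array(0, c(4, 4, 33))
  for (i in 1:4) for (j in 1:4)
    cb[i, j, ] <- if ((i + j) %% 2 == 0) a else b
  res <- downsample_2x2(spectral_image(cb, wl))
  for (i in 1:2) for (j in 1:2)
    expect_equal(res$values[i, j, ], (a + b) / 2)
})

test_that("dark-offset subtraction clips at zero and flags bad offsets", {
  img <- tiny_image()
  expect_identical(subtract_dark_offset(img, 0)$values, img$values)
  # constructed inverse: add a known constant, then remove it
  shifted <- spectral_image(img$values + 0.05, img$wavelengths)
  rec <- subtract_dark_offset(shifted, 0.05)
  expect_equal(rec$values, img$values, tolerance = 1e-12)
  # per-band minimum offset zeroes each band's minimum
  m <- conegain:::pixel_matrix(img)
  rec2 <- subtract_dark_offset(img, apply(m, 2, min))
  expect_equal(apply(conegain:::pixel_matrix(rec2), 2, min), rep(0, 33))
  expect_error(subtract_dark_offset(img, 10), "99th percentile")
  expect_s3_class(subtract_dark_offset(img, 10, force = TRUE),
                  "spectral_image")
})

test_that("pixel sampling is seeded, uniform, and records provenance", {
  img <- tiny_image()
  s1 <- sample_spectra(img, 10, seed = 4)
  s2 <- sample_spectra(img, 10, seed = 4)
  expect_identical(s1$spectra, s2$spectra)
  expect_identical(s1$provenance$pixel_index, s2$provenance$pixel_index)
  s3 <- sample_spectra(img, 10, seed = 5)
  expect_false(identical(s1$provenance$pixel_index,
                         s3$provenance$pixel_index))
  # without replacement at full size: a permutation of all pixels
  all24 <- sample_spectra(img, 24, seed = 1, replace = FALSE)
  expect_setequal(all24$provenance$pixel_index, 1:24)
  expect_error(sample_spectra(img, 25, seed = 1, replace = FALSE), "exceeds")
  expect_error(sample_spectra(img, 0), "positive")
})

test_that("upper-half cropping removes sky rows", {
  img <- tiny_image()
  wl <- img$wavelengths
  sky <- rep(9, 33)
  vals <- img$values
  vals[1:2, , ] <- rep(sky, each = 2 * 6)
  scene <- spectral_image(vals, wl)
  crop <- crop_upper_half(scene)
  expect_equal(dim(crop)[1], 2)
  expect_equal(crop$values, img$values[3:4, , , drop = FALSE])
  expect_false(any(apply(conegain:::pixel_matrix(crop), 1,
                         function(r) all(r == 9))))
  one_row <- spectral_image(vals[1, , , drop = FALSE], wl)
  expect_error(crop_upper_half(one_row), "at least 2 rows")
  # odd height keeps the lower ceiling(h/2)
  odd <- spectral_image(vals[1:3, , , drop = FALSE], wl)
  expect_equal(dim(crop_upper_half(odd))[1], 2)
})
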
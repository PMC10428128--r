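test_that("daylight spectra sit on the daylight locus and behave with CCT", {
  for (cct in c(5000, 6500, 10000)) {
    d <- daylight_spectrum(cct)
    xy <- conegain:::xyz_to_xy(spectrum_to_xyz(d))
    locus <- daylight_chromaticity(cct)
    expect_lt(abs(xy[1, "x"] - locus["x"]), 1e-3)
    expect_lt(abs(xy[1, "y"] - locus["y"]), 1e-3)
    expect_equal(d$values[d$wavelengths == 560], 100)
  }
  ratio <- function(s) s$values[s$wavelengths == 450] /
    s$values[s$wavelengths == 650]
  expect_gt(ratio(daylight_spectrum(10000)), ratio(daylight_spectrum(6500)))
  expect_error(daylight_spectrum(3000), "4000")
})

test_that("reflectance_from_basis clips, stays smooth, and handles edges", {
  wl <- seq(400, 720, by = 10)
  b <- reflectance_basis(wl)
  flat <- reflectance_from_basis(c(1, rep(0, 6)), b, wl)
  expect_equal(flat$values, rep(0.5, 33))
  expect_message(big <- reflectance_from_basis(c(4, rep(0, 6)), b, wl),
                 "clipped")
  expect_true(all(big$values <= 1))
  expect_error(reflectance_from_basis(c(1, 0), b, wl), "mismatch")
  set.seed(5)
  for (i in 1:200) {
    w <- c(runif(1, 0.2, 1.6), rnorm(6, 0, 0.3))
    r <- suppressMessages(reflectance_from_basis(w, b, wl))
    expect_true(all(r$values >= 0 & r$values <= 1))
    expect_lt(max(abs(diff(r$values))), 0.5)
  }
})

test_that("generated scenes recover the requested color statistics", {
  img <- generate_scene(scene_spec(width = 128, height = 128,
                                   target_shares = c(0.77, 0.08, 0.15),
                                   seed = 1))
  u <- scene_ucs(img)
  shares <- variance_partition(u)
  expect_lt(max(abs(shares - c(0.77, 0.08, 0.15))), 0.05)
  ax <- major_chromatic_axis(u)
  expect_lt(min(abs(ax$phi - 90), 180 - abs(ax$phi - 90)), 5)
  # same spec, same seed: bit-identical
  img2 <- generate_scene(scene_spec(width = 128, height = 128,
                                    target_shares = c(0.77, 0.08, 0.15),
                                    seed = 1))
  expect_identical(img$values, img2$values)
})

test_that("variance-share recovery holds across a grid of targets", {
  grid <- list(c(0.85, 0.05, 0.10), c(0.70, 0.10, 0.20),
               c(0.77, 0.15, 0.08), c(0.60, 0.15, 0.25))
  axes <- c(90, 100, 20, 120)  # axis must agree with the rg/yb ordering
  errs <- mapply(function(sh, ax, s) {
    img <- generate_scene(scene_spec(width = 64, height = 64,
                                     target_shares = sh,
                                     chromatic_axis_deg = ax, seed = s))
    max(abs(variance_partition(scene_ucs(img)) - sh))
  }, grid, axes, seq_along(grid))
  expect_lt(mean(errs), 0.05)
})

test_that("a pure-lightness target yields an achromatic scene", {
  g <- generate_scene(scene_spec(width = 48, height = 48,
                                 target_shares = c(1, 0, 0), seed = 2))
  u <- scene_ucs(g)
  expect_lt(stats::sd(u$a), 0.2)
  expect_lt(stats::sd(u$b), 0.2)
  expect_gt(stats::sd(u$J), 5)
})

test_that("unreachable share/axis combinations are signalled", {
  # axis on the rg direction but yb variance dominant: geometrically
  # impossible for a 2x2 covariance
  expect_error(conegain:::chromatic_cov_structure(
    c(lightness = 0.7, rg = 0.05, yb = 0.25), 0), "unreachable")
  expect_error(generate_scene(scene_spec(target_shares = c(0.02, 0.49, 0.49),
                                         seed = 1)), "unreachable")
})

test_that("material frequency entropy is non-increasing in frequency_skew", {
  ent <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log(p)) }
  mean_ent <- sapply(c(0, 0.8, 1.6, 2.4), function(sk) {
    mean(sapply(1:3, function(s) {
      img <- generate_scene(scene_spec(width = 48, height = 48,
                                       frequency_skew = sk, seed = s))
      ent(img$metadata$material_counts)
    }))
  })
  expect_true(all(diff(mean_ent) <= 1e-9))
})

test_that("palettes are near-uniform, deterministic, and span the gamut", {
  pal <- generate_palette(200, seed = 3)
  expect_identical(vapply(pal, function(s) s$values, numeric(33)),
                   vapply(generate_palette(200, seed = 3),
                          function(s) s$values, numeric(33)))
  u <- scene_ucs(palette_radiance_set(pal))
  # nearest-neighbour spacing: coefficient of variation below 0.5
  d <- as.matrix(stats::dist(cbind(u$J, u$a, u$b)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(stats::sd(nn) / mean(nn), 0.5)
  # spans lightness and hue
  expect_gt(diff(range(u$J)), 40)
  expect_gt(diff(range(atan2(u$b, u$a))), 4)
  # chromatic share exceeds a natural-like scene's
  pal_shares <- variance_partition(u)
  scene_shares <- variance_partition(scene_ucs(small_scene()))
  expect_gt(pal_shares["rg"] + pal_shares["yb"],
            scene_shares["rg"] + scene_shares["yb"])
  # degenerate gamut: achromatic lightness series
  gray <- generate_palette(8, gamut_scale = 0, seed = 1)
  ug <- scene_ucs(palette_radiance_set(gray))
  expect_true(all(sqrt(ug$a^2 + ug$b^2) < 1))
  expect_equal(length(unique(round(ug$J, 4))), 8)
  expect_error(generate_palette(5), "at least 8")
})
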
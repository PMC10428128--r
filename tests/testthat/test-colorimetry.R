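test_that("tristimulus integration behaves on reference inputs", {
  wl <- seq(400, 720, 10)
  expect_equal(unname(spectrum_to_xyz(spectrum(wl, rep(0, 33)))),
               c(0, 0, 0))
  # equal-energy white lands near (1/3, 1/3)
  xy <- conegain:::xyz_to_xy(spectrum_to_xyz(spectrum(wl, rep(1, 33))))
  expect_lt(abs(xy[1, "x"] - 1 / 3), 0.01)
  expect_lt(abs(xy[1, "y"] - 1 / 3), 0.01)
  expect_error(spectrum_to_xyz(matrix(1, 2, 21), seq(500, 700, 10)),
               "cover")
})

test_that("the CIECAM02 forward model reproduces the standard example", {
  # CIE 159:2004 worked example: D65-like white, LA = 318.31, Yb = 20,
  # average surround, adaptation as computed by the model
  vc <- viewing_conditions(
    white_xy = conegain:::xyz_to_xy(c(95.05, 100, 108.88)),
    la = 318.31, yb = 20, discount_illuminant = FALSE)
  out <- xyz_to_cam02ucs(c(19.01, 20.00, 21.78), vc)
  cam <- attr(out, "cam")
  expect_equal(cam$J_cam, 41.73, tolerance = 0.1)
  expect_equal(cam$C, 0.1047, tolerance = 0.01)
  expect_equal(cam$h, 219.05, tolerance = 0.5)
})

test_that("the adapting white and neutral series are achromatic", {
  vc <- viewing_conditions()
  w <- conegain:::xyy_to_xyz(vc$white_xy[1], vc$white_xy[2], 100)
  u <- xyz_to_cam02ucs(w, vc)
  expect_lt(abs(u$a), 0.5)
  expect_lt(abs(u$b), 0.5)
  grays <- xyz_to_cam02ucs(conegain:::xyy_to_xyz(
    rep(vc$white_xy[1], 5), rep(vc$white_xy[2], 5),
    c(5, 20, 40, 70, 100)), vc)
  expect_true(all(abs(grays$a) < 0.5 & abs(grays$b) < 0.5))
  expect_true(all(diff(grays$J) > 0))
  # negative tristimulus flagged
  expect_gt(attr(xyz_to_cam02ucs(c(-1, 5, 5), vc), "flagged"), 0)
})

test_that("variance partition and chroma ratios follow their definitions", {
  pts <- data.frame(J = rnorm(500, 50, 10), a = 0, b = 0)
  expect_equal(unname(variance_partition(pts)), c(1, 0, 0))
  set.seed(51)
  iso <- data.frame(J = rnorm(4000), a = rnorm(4000), b = rnorm(4000))
  expect_lt(max(abs(variance_partition(iso) - 1 / 3)), 0.05)
  expect_equal(sum(variance_partition(iso)), 1)
  expect_error(variance_partition(data.frame(J = c(1, 1), a = c(0, 0),
                                             b = c(0, 0))), "zero total")
  expect_equal(chroma_lightness_ratio(data.frame(J = 10, a = 3, b = 4)), 0.5)
  expect_equal(chroma_lightness_ratio(data.frame(J = c(5, 9), a = 0, b = 0)),
               0)
  expect_error(chroma_lightness_ratio(data.frame(J = 0, a = 1, b = 1)),
               "J > 0")
})

test_that("the major chromatic axis matches eigen closed forms and rotates", {
  on_a <- data.frame(J = 1, a = c(-2, -1, 0, 1, 2), b = 0)
  expect_equal(major_chromatic_axis(on_a)$phi, 0)
  on_b <- data.frame(J = 1, a = 0, b = c(-2, -1, 0, 1, 2))
  expect_equal(major_chromatic_axis(on_b)$phi, 90)
  # covariance [[2,1],[1,1]]: closed-form angle atan2(2, 1) / 2
  set.seed(52)
  z <- matrix(rnorm(2 * 20000), ncol = 2)
  L <- chol(matrix(c(2, 1, 1, 1), 2))
  ab <- z %*% L
  pts <- data.frame(J = 1, a = ab[, 1], b = ab[, 2])
  expect_equal(major_chromatic_axis(pts)$phi, atan2(2, 1) * 90 / pi,
               tolerance = 1)
  # rotation equivariance
  th <- 37 * pi / 180
  rot <- data.frame(J = 1,
                    a = ab[, 1] * cos(th) - ab[, 2] * sin(th),
                    b = ab[, 1] * sin(th) + ab[, 2] * cos(th))
  expect_equal((major_chromatic_axis(rot)$phi - major_chromatic_axis(pts)$phi)
               %% 180, 37, tolerance = 0.1)
  iso <- data.frame(J = 1, a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_error(major_chromatic_axis(iso), "isotropic")
})

test_that("confusion axes reproduce the dichromatic directions", {
  vc <- viewing_conditions()
  expect_equal(confusion_axis_direction("protan", vc), 12, tolerance = 3)
  expect_equal(confusion_axis_direction("deutan", vc), 178, tolerance = 3)
  expect_equal(confusion_axis_direction("tritan", vc), 114, tolerance = 3)
  expect_equal(confusion_axis_direction("protan", vc, orthogonal = TRUE),
               102, tolerance = 3)
  expect_equal(confusion_axis_direction("deutan", vc, orthogonal = TRUE),
               88, tolerance = 3)
  expect_equal(confusion_axis_direction("tritan", vc, orthogonal = TRUE),
               24, tolerance = 3)
  # stable over two orders of magnitude of the finite-difference step
  steps <- c(1e-4, 1e-3, 1e-2)
  phis <- sapply(steps, function(s)
    confusion_axis_direction("protan", vc, step = s))
  expect_lt(max(phis) - min(phis), 0.5)
})
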
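test_that("shipped fundamentals peak at the assumed wavelengths", {
  f <- load_fundamentals()
  expect_lt(abs(f$L$lambda_max - 559), 2)
  expect_lt(abs(f$M$lambda_max - 530), 2)
  expect_lt(abs(f$S$lambda_max - 426), 2)
  for (cl in f) expect_equal(max(cl$sensitivity), 1)
  # coverage gap is fatal
  tab <- cone_fundamental_table(seq(450, 780, 1))
  expect_error(load_fundamentals(tab), "cover")
})

test_that("excitations match a fine-grid quadrature oracle and are linear", {
  wl <- seq(400, 720, by = 10)
  obs <- make_observer("normal")
  set.seed(3)
  # smooth random spectra
  b <- reflectance_basis(wl)
  sp <- t(replicate(5, as.numeric(b %*% c(runif(1, 0.5, 1.5),
                                          rnorm(6, 0, 0.3)))))
  sp <- pmax(sp, 0)
  ss <- spectral_set(sp, wl)
  q <- cone_excitations(ss, obs)
  expect_true(all(q >= 0))
  # 1-nm refined quadrature oracle via spline-interpolated spectra
  fine <- seq(400, 720, by = 1)
  for (i in 1:5) {
    spf <- stats::spline(wl, sp[i, ], xout = fine)$y
    for (cn in c("L", "M", "S")) {
      Sf <- stats::spline(obs$cones[[cn]]$wavelengths,
                          obs$cones[[cn]]$sensitivity, xout = fine)$y
      oracle <- sum(conegain:::trapezoid_weights(fine) * spf * Sf)
      expect_lt(abs(q[i, cn] - oracle) / oracle, 0.01)
    }
  }
  # linearity
  q12 <- cone_excitations(spectral_set(rbind(2 * sp[1, ] + 3 * sp[2, ]), wl),
                          obs)
  expect_equal(as.numeric(q12), as.numeric(2 * q[1, ] + 3 * q[2, ]),
               tolerance = 1e-10)
  # zero spectrum maps to zero excitation
  q0 <- cone_excitations(spectral_set(rbind(rep(0, 33), rep(1, 33)), wl), obs)
  expect_equal(as.numeric(q0[1, ]), c(0, 0, 0))
  # monochromatic line near 426 nm drives S hardest relative to its peak
  line <- rep(0, 33); line[wl == 430] <- 1
  ql <- cone_excitations(spectral_set(rbind(line, line), wl), obs)
  expect_equal(unname(which.max(ql[1, ])), 3)
})

test_that("pigment shifting lands hybrids on target and composes", {
  f <- load_fundamentals()
  h_prot <- shift_pigment(f$M, 536)
  h_deut <- shift_pigment(f$L, 549)
  expect_lt(abs(h_prot$lambda_max - 536), 1)
  expect_lt(abs(h_deut$lambda_max - 549), 1)
  # zero shift returns the smoothed template
  z <- shift_pigment(f$L, f$L$lambda_max)
  sm <- conegain:::smooth_template(f$L)
  smoothed <- pmax(stats::predict(sm$fit), 0)
  expect_lt(max(abs(z$sensitivity - smoothed / max(smoothed))), 0.01)
  # +delta then -delta recovers the smoothed template
  fwd <- shift_pigment(f$L, 549)
  back <- shift_pigment(fwd, f$L$lambda_max)
  expect_lt(max(abs(back$sensitivity - z$sensitivity)), 0.01)
  expect_error(shift_pigment(f$L, 600), "35 nm")
})

test_that("observers carry the assumed pigment complements", {
  expect_equal(vapply(make_observer("normal")$cones,
                      function(c) c$lambda_max, numeric(1)),
               c(L = 559, M = 530, S = 425.8), tolerance = 0.01)
  pro <- make_observer("protanope")
  expect_length(pro$cones, 2)
  expect_false(any(abs(vapply(pro$cones, function(c) c$lambda_max,
                              numeric(1)) - 559) < 5))
  expect_length(make_observer("deuteranope")$cones, 2)
  pa <- make_observer("protanomal")
  expect_equal(unname(vapply(pa$cones, function(c) c$lambda_max,
                             numeric(1))[1:2]), c(536, 530), tolerance = 1)
  expect_equal(pa$cones$L$class_name, "L")  # hybrid takes its slot's noise
  mm <- make_observer("m_monochromat")
  expect_length(mm$cones, 1)
  expect_equal(mm$cones$M$lambda_max, 530, tolerance = 1)
  expect_error(make_observer("tritanope"))
})

test_that("cone noise is Weber-scaled, class-ratioed, and unbiased", {
  nm <- noise_model(weber_l = 0.02)
  obs <- make_observer("normal")
  q <- matrix(rep(c(5, 2, 0.5), each = 1e5), ncol = 3,
              dimnames = list(NULL, c("L", "M", "S")))
  y <- add_cone_noise(q, obs, nm, seed = 8)
  rel_sd <- apply((y - q) / q, 2, sd)
  expect_lt(abs(rel_sd[["L"]] - 0.02), 0.001)
  expect_lt(abs(rel_sd[["S"]] / rel_sd[["L"]] - 0.087 / 0.018),
            0.02 * (0.087 / 0.018))
  expect_lt(abs(rel_sd[["M"]] / rel_sd[["L"]] - 0.019 / 0.018), 0.03)
  # unbiased: mean of replicates converges to q
  expect_lt(max(abs(colMeans(y) - q[1, ]) / q[1, ]), 3 * 0.1 / sqrt(1e5))
  # zero excitation stays exactly zero
  y0 <- add_cone_noise(matrix(0, 10, 3), obs, nm, seed = 1)
  expect_true(all(y0 == 0))
  # determinism
  expect_identical(add_cone_noise(q[1:10, ], obs, nm, seed = 3),
                   add_cone_noise(q[1:10, ], obs, nm, seed = 3))
  expect_error(noise_model(weber_l = 0), "positive")
})
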
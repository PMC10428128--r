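test_that("KL entropy matches closed forms in one dimension", {
  set.seed(21)
  n <- 8000
  expect_lt(abs(kl_entropy(runif(n), 3)), 0.05)
  expect_lt(abs(kl_entropy(rnorm(n), 3) - 0.5 * log2(2 * pi * exp(1))), 0.05)
  # scaling law: doubling every coordinate adds d bits
  x <- matrix(rnorm(2 * 3000), ncol = 2)
  expect_equal(kl_entropy(2 * x, 3) - kl_entropy(x, 3), 2, tolerance = 0.05)
  expect_error(kl_entropy(rnorm(10), 10), "k < n")
  expect_error(kl_entropy(matrix(rnorm(20), 4, 5)), "dimension")
  # duplicates are jittered deterministically, not fatal
  dup <- c(rnorm(500), rep(1, 3))
  expect_message(h1 <- kl_entropy(dup), "jitter")
  expect_identical(h1, suppressMessages(kl_entropy(dup)))
})

test_that("kNN mutual information matches Gaussian closed forms", {
  set.seed(22)
  n <- 6000
  x <- rnorm(n)
  # independence
  expect_lt(abs(kl_mutual_information(x, rnorm(n), seed = 1,
                                      se_reps = 0)$bits), 0.1)
  # correlated pair and additive channel at default k
  rho <- 0.8
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_equal(kl_mutual_information(x, y, seed = 1, se_reps = 0)$bits,
               -0.5 * log2(1 - rho^2), tolerance = 0.1)
  y2 <- x + rnorm(n) / 3
  expect_equal(kl_mutual_information(x, y2, seed = 1, se_reps = 0)$bits,
               0.5 * log2(1 + 9), tolerance = 0.1)
  # degenerate input returns zero with a warning
  expect_warning(z <- kl_mutual_information(rep(1, 100), rnorm(100)),
                 "degenerate")
  expect_equal(z$bits, 0)
})

test_that("the channel estimator agrees with independent oracles", {
  # 1-D: deterministic quadrature of the exact mixture output density
  set.seed(30)
  q <- matrix(exp(rnorm(400, log(5), 0.6)), ncol = 1)
  w <- 0.05
  grid <- seq(1e-3, max(q) * 1.4, length.out = 6000)
  f <- rowMeans(vapply(seq_len(nrow(q)), function(i) {
    stats::dnorm(grid, q[i, 1], w * q[i, 1])
  }, numeric(length(grid))))
  h_y_quad <- -sum(f * log2(pmax(f, 1e-300))) * diff(grid[1:2])
  i_quad <- h_y_quad - (0.5 * log2(2 * pi * exp(1)) + log2(w) +
                        mean(log2(q)))
  set.seed(31)
  y <- q * (1 + w * rnorm(nrow(q)))
  est <- conegain:::channel_information(q, y, w, offset = FALSE, se_reps = 0)
  expect_equal(est$bits, i_quad, tolerance = 0.1)

  # scene case: matches the Monte-Carlo mixture oracle per observer
  img <- small_scene()
  allpix <- as_spectral_set(img)
  nm <- noise_model()
  for (ob in c("normal", "deuteranomal", "protanope", "m_monochromat")) {
    obs <- make_observer(ob)
    oracle <- channel_oracle(allpix, obs, nm)
    est <- scene_information(img, obs, nm, n = nrow(allpix$spectra),
                             seed = 4, se_reps = 2)
    expect_lt(abs(est$bits - oracle), 0.15)
    expect_gt(est$bits, 0)
  }
})

test_that("channel and kNN routes agree where the kNN route is reliable", {
  # same estimation problem I(q; Y) posed to both routes in one
  # dimension at moderate noise, where the generic kNN estimator is
  # trustworthy
  img <- small_scene()
  obs <- make_observer("m_monochromat")
  nm <- noise_model(weber_l = 0.3)
  ss <- conegain:::scene_sample(img, 2000, 2)
  q <- cone_excitations(ss, obs)
  w <- conegain:::observer_webers(obs, nm)
  y <- q * (1 + w * conegain:::noise_field(nrow(q), 3L)[, "M"])
  a <- conegain:::channel_information(q, y, w, se_reps = 2, seed = 5)
  b <- kl_mutual_information(q, y, k = 3, se_reps = 2, seed = 5)
  expect_lt(abs(a$bits - b$bits),
            0.15 + 3 * sqrt(a$se^2 + b$se_bits^2))
})

test_that("paired losses are exact for identical observers and consistent", {
  img <- small_scene()
  same <- information_loss(img, "normal", n = 1200, seed = 3, se_reps = 0)
  expect_identical(same$bits, 0)
  dl <- information_loss(img, "deuteranope", n = 1200, seed = 3, se_reps = 2)
  expect_equal(dl$bits, dl$reference_bits - dl$deficient_bits)
  expect_equal(dl$percent_surface_reduction, 100 * (1 - 2^(-dl$bits)))
  # an achromatic scene leaves a dichromat almost nothing to lose: only
  # the noise-pooling advantage of a third redundant lightness sample
  # remains, far below the chromatic losses of a natural-like scene
  g <- generate_scene(scene_spec(width = 48, height = 48,
                                 target_shares = c(1, 0, 0), seed = 7))
  dg <- information_loss(g, "protanope", n = 1200, seed = 5, se_reps = 3)
  expect_gt(dg$bits, -3 * dg$se_bits)
  # high-SNR pooling limit: 0.5 * log2(sum of all 1/w_c^2 over the
  # deficient subset's sum) bounds the achromatic loss
  w <- conegain:::observer_webers(make_observer("normal"), noise_model())
  pool <- 0.5 * log2(sum(1 / w^2) / sum(1 / w[c("M", "S")]^2))
  expect_lt(dg$bits, pool + 0.15)
  natural <- information_loss(small_scene(), "protanope", n = 1200,
                              seed = 5, se_reps = 0)
  expect_lt(dg$bits, natural$bits)
})

test_that("palette inputs use every available spectrum", {
  pal <- generate_palette(120, seed = 2)
  est <- scene_information(palette_radiance_set(pal), "normal", n = 50,
                           seed = 1, se_reps = 0)
  expect_equal(est$n, 120)  # n is ignored for sets: all spectra used
})

test_that("losses grow as cone noise falls", {
  img <- small_scene()
  d_low <- information_loss(img, "protanope", noise_model(0.01),
                            n = 1200, seed = 2, se_reps = 0)
  d_mid <- information_loss(img, "protanope", noise_model(0.02),
                            n = 1200, seed = 2, se_reps = 0)
  d_high <- information_loss(img, "protanope", noise_model(0.05),
                             n = 1200, seed = 2, se_reps = 0)
  expect_gt(d_low$bits, d_mid$bits)
  expect_gt(d_mid$bits, d_high$bits)
})

test_that("effective surface counts follow 2^I", {
  expect_equal(effective_surfaces(0), 1)
  expect_equal(effective_surfaces(1), 2)
  expect_equal(effective_surfaces(5.9), 2^5.9)
  expect_equal(100 * (1 - 2^(-0.6)), 34.02, tolerance = 0.01)
  expect_error(effective_surfaces(-1), "non-negative")
})

test_that("stability reports shrink with sample size and reproduce", {
  img <- small_scene()
  fn <- function(ss) scene_information(ss, "deuteranope", se_reps = 0,
                                       seed = 1)$bits
  rep1 <- stability_check(fn, img, subset_fracs = c(0.25, 1), reps = 10,
                          seed = 2, n_base = 800)
  rep2 <- stability_check(fn, img, subset_fracs = c(0.25, 1), reps = 10,
                          seed = 2, n_base = 800)
  expect_identical(rep1$table, rep2$table)
  expect_lt(rep1$table$sd[2], rep1$table$sd[1])
  expect_true(is.logical(rep1$stable))
  expect_error(stability_check(fn, img, reps = 5), "at least 10")
})
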
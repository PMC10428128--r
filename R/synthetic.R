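# Synthetic hyperspectral scenes, palettes, and illuminants with the
# color statistics the analysis assumes: dominant lightness variance,
# small chromatic variance concentrated along a controllable axis, a
# bounded gamut, and strongly uneven surface frequencies.

#' Specification of a synthetic hyperspectral scene
#'
#' Defaults emulate the natural-scene statistics the analysis targets:
#' about 77% of CAM02-UCS variance in lightness, 8% in redness-greenness
#' and 15% in yellowness-blueness, a major chromatic axis near the
#' yellowness-blueness direction (90 degrees), strongly uneven surface
#' frequencies (Zipf exponent 1), and a median chroma-to-lightness ratio
#' near 0.25.
#'
#' @param width,height scene size in pixels.
#' @param wavelengths nm grid (default 400-720 at 10 nm, 33 bands).
#' @param n_materials distinct surface reflectances (>= 2).
#' @param frequency_skew Zipf exponent >= 0 for material frequencies
#'   (0 = uniform; larger = more uneven).
#' @param target_shares desired fractions of CAM02-UCS variance
#'   (lightness, rg, yb), summing to 1.
#' @param chromatic_axis_deg major chromatic axis direction in
#'   \[0, 180), degrees anticlockwise from a'_M.
#' @param gamut_scale chroma multiplier bounding the reachable gamut.
#' @param illuminant_cct illuminant correlated color temperature, K.
#' @param target_chroma_lightness median chroma/lightness ratio to
#'   calibrate toward, or `NA` to leave the default colorfulness.
#' @param shading_sdlog log-sd of the smoothed log-normal shading field.
#' @param sensor_noise relative per-band measurement noise added to the
#'   radiances (keeps spectra full-rank, as camera noise does).
#' @param landcover metadata tag.
#' @param seed integer seed; scenes are bit-reproducible given the spec.
#' @return Object of class `"scene_spec"`.
#' @export
scene_spec <- function(width = 128, height = 128,
                       wavelengths = seq(400, 720, by = 10),
                       n_materials = 32, frequency_skew = 1,
                       target_shares = c(lightness = 0.77, rg = 0.08,
                                         yb = 0.15),
                       chromatic_axis_deg = 90, gamut_scale = 1,
                       illuminant_cct = 6500,
                       target_chroma_lightness = 0.25,
                       shading_sdlog = 0.35, sensor_noise = 0.003,
                       landcover = "unknown", seed = 1) {
  target_shares <- as.numeric(target_shares)
  if (length(target_shares) != 3 || abs(sum(target_shares) - 1) > 1e-9)
    stop("target_shares must be three fractions summing to 1")
  if (any(target_shares < 0)) stop("target_shares must be non-negative")
  check_wavelengths(wavelengths)
  if (n_materials < 2) stop("need at least 2 materials")
  if (frequency_skew < 0) stop("frequency_skew must be >= 0")
  if (chromatic_axis_deg < 0 || chromatic_axis_deg >= 180)
    stop("chromatic_axis_deg must lie in [0, 180)")
  structure(list(width = width, height = height,
                 wavelengths = as.numeric(wavelengths),
                 n_materials = n_materials,
                 frequency_skew = frequency_skew,
                 target_shares = c(lightness = target_shares[1],
                                   rg = target_shares[2],
                                   yb = target_shares[3]),
                 chromatic_axis_deg = chromatic_axis_deg,
                 gamut_scale = gamut_scale,
                 illuminant_cct = illuminant_cct,
                 target_chroma_lightness = target_chroma_lightness,
                 shading_sdlog = shading_sdlog,
                 sensor_noise = sensor_noise,
                 landcover = landcover, seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(paste0("<scene_spec: %dx%d px, %d bands, %d materials, ",
                     "shares %.2f/%.2f/%.2f, axis %g deg, skew %g, seed %d>\n"),
              x$height, x$width, length(x$wavelengths), x$n_materials,
              x$target_shares[1], x$target_shares[2], x$target_shares[3],
              x$chromatic_axis_deg, x$frequency_skew, x$seed))
  invisible(x)
}

#' Smooth low-dimensional reflectance basis
#'
#' Seven basis functions: a constant at 0.5 followed by six Gaussian
#' bumps spanning the grid, giving generated reflectances the smoothness
#' and low dimensionality of natural reflectance spectra.
#'
#' @param wavelengths nm grid.
#' @return `bands x 7` matrix.
#' @export
reflectance_basis <- function(wavelengths = seq(400, 720, by = 10)) {
  mus <- seq(min(wavelengths) + 15, max(wavelengths) - 15, length.out = 6)
  bumps <- vapply(mus, function(mu) exp(-0.5 * ((wavelengths - mu) / 55)^2),
                  numeric(length(wavelengths)))
  cbind(const = rep(0.5, length(wavelengths)), bumps)
}

#' Reflectance from basis weights
#'
#' `clip(B w, 0, 1)`; clipping is reported via `message()`. The basis
#' must be smooth enough that adjacent-band jumps stay below 0.5, which
#' the default [reflectance_basis()] guarantees for weights of ordinary
#' size.
#'
#' @param weights coefficient vector, one entry per basis function.
#' @param basis `bands x m` matrix on the scene grid.
#' @param wavelengths nm grid of the basis.
#' @return A reflectance [spectrum()].
#' @export
reflectance_from_basis <- function(weights, basis,
                                   wavelengths = seq(400, 720, by = 10)) {
  if (length(weights) != ncol(basis))
    stop("weight/basis dimension mismatch")
  v <- as.numeric(basis %*% weights)
  n_clip <- sum(v < 0 | v > 1)
  if (n_clip > 0)
    message(sprintf("reflectance_from_basis: clipped %d band values", n_clip))
  spectrum(wavelengths, pmin(pmax(v, 0), 1), kind = "reflectance")
}

# Zipf-like material frequencies: p_i proportional to i^(-skew)
zipf_weights <- function(n, skew) {
  p <- seq_len(n)^(-skew)
  p / sum(p)
}

# spatially smoothed standard-normal field (separable moving-average
# blur), standardized to zero mean unit sd
smooth_field <- function(h, w, blur = 5, passes = 3) {
  f <- matrix(stats::rnorm(h * w), h, w)
  kern <- rep(1 / blur, blur)
  for (p in seq_len(passes)) {
    f <- apply(f, 2, function(col) stats::filter(col, kern, circular = TRUE))
    f <- t(apply(f, 1, function(row) stats::filter(row, kern, circular = TRUE)))
  }
  (f - mean(f)) / stats::sd(f)
}

# target 2x2 chromatic covariance (relative units) from shares and axis;
# errors when the (shares, axis) pair is geometrically unreachable
chromatic_cov_structure <- function(shares, phi_deg) {
  va <- shares["rg"]; vb <- shares["yb"]
  c2 <- cos(2 * phi_deg * pi / 180)
  if (abs(c2) < 1e-9) {
    if (abs(va - vb) > 1e-9 * (va + vb))
      stop("unreachable target_shares: a 45/135-degree axis requires equal ",
           "rg and yb variance")
    dl <- (va + vb) / 3  # anisotropy is undetermined here; use a moderate one
  } else {
    dl <- (va - vb) / c2
  }
  if (dl < 0 || dl > va + vb + 1e-12)
    stop("unreachable target_shares for chromatic_axis_deg = ", phi_deg)
  l1 <- (va + vb + dl) / 2; l2 <- (va + vb - dl) / 2
  cs <- cos(phi_deg * pi / 180); sn <- sin(phi_deg * pi / 180)
  R <- matrix(c(cs, sn, -sn, cs), 2, 2)
  R %*% diag(c(l1, l2)) %*% t(R)
}

mat_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2) %*% t(e$vectors)
}

# CAM02-UCS of reflectance rows under an illuminant, anchored so that a
# perfect white (reflectance 1) maps to the adapting white's Y = 100
ucs_of_reflectance <- function(refl, illum, viewing) {
  rad <- sweep(rbind(refl), 2, illum$values, `*`)
  xyz <- spectrum_to_xyz(rad, illum$wavelengths)
  ywhite <- spectrum_to_xyz(illum)[["Y"]]
  xyz_to_cam02ucs(xyz * (100 / ywhite), viewing)
}

# minimum-norm preimage of unit (a, b) displacements in basis-weight
# space, linearized about the neutral reflectance
chromatic_preimage <- function(basis, neutral, illum, viewing, delta = 0.05) {
  m <- ncol(basis) - 1
  base_ucs <- ucs_of_reflectance(neutral, illum, viewing)
  J <- matrix(0, 2, m)
  for (j in seq_len(m)) {
    r <- pmin(pmax(neutral + delta * basis[, j + 1], 0), 1)
    u <- ucs_of_reflectance(r, illum, viewing)
    J[, j] <- c(u$a - base_ucs$a, u$b - base_ucs$b) / delta
  }
  t(J) %*% solve(J %*% t(J) + diag(1e-9, 2))
}

#' Generate a synthetic hyperspectral scene
#'
#' Builds a radiance image as (material reflectance) x (illuminant) x
#' (smoothed log-normal per-pixel shading), with material frequencies
#' drawn from a Zipf law with exponent `frequency_skew` and a small
#' relative per-band sensor noise. Material chromaticities are placed by
#' inverting a local linearization of the CAM02-UCS mapping, and an
#' internal calibration loop rescales the chromatic covariance (and,
#' when requested, the mean colorfulness) until the realized CAM02-UCS
#' variance shares match `target_shares`; the loop signals an error
#' rather than silently clamping when the targets are unreachable for
#' the given `gamut_scale`.
#'
#' @param spec a [scene_spec()].
#' @param viewing [viewing_conditions()] used by the internal
#'   calibration (the same defaults as [scene_ucs()]).
#' @return A [spectral_image()]; deterministic given `spec` (including
#'   its seed).
#' @export
generate_scene <- function(spec, viewing = viewing_conditions()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, generate_scene_impl(spec, viewing))
}

generate_scene_impl <- function(spec, viewing) {
  wl <- spec$wavelengths
  illum <- daylight_spectrum(spec$illuminant_cct, wl)
  basis <- reflectance_basis(wl)
  neutral <- basis[, 1] * 0.6  # flat 0.30 reflectance
  K <- spec$n_materials
  npix <- spec$height * spec$width

  # fixed random draws, reused across calibration iterations
  z <- matrix(stats::rnorm(2 * K), K, 2)             # material chromatic coords
  g <- exp(stats::rnorm(K, log(0.35), 0.45))         # material lightness scales
  g <- pmin(pmax(g, 0.05), 0.95)
  freq <- zipf_weights(K, spec$frequency_skew)
  mat_idx <- sample.int(K, npix, replace = TRUE, prob = freq)
  shade <- exp(spec$shading_sdlog * smooth_field(spec$height, spec$width))
  shade <- as.numeric(shade) / mean(shade)
  band_noise <- matrix(stats::rnorm(npix * length(wl)), npix, length(wl))

  s_chrom <- spec$target_shares[["rg"]] + spec$target_shares[["yb"]]
  achromatic <- s_chrom < 1e-9
  P <- if (achromatic) NULL else
    chromatic_preimage(basis, neutral, illum, viewing)

  build_pixels <- function(cc, mu) {
    refl <- t(vapply(seq_len(K), function(i) {
      chroma <- if (achromatic) 0 else
        as.numeric(basis[, -1] %*% (P %*% (mu + cc[i, ])))
      pmin(pmax(g[i] * pmin(pmax(neutral + chroma, 0.01), 1), 0), 1)
    }, numeric(length(wl))))
    rad <- refl[mat_idx, , drop = FALSE] * shade
    rad <- sweep(rad, 2, illum$values, `*`)
    rad * (1 + spec$sensor_noise * band_noise)
  }
  probe_ucs <- function(rad) {
    idx <- round(seq(1, npix, length.out = min(6000, npix)))
    xyz <- spectrum_to_xyz(rad[idx, , drop = FALSE], wl)
    yref <- stats::quantile(xyz[, 2], 0.99, names = FALSE)
    xyz_to_cam02ucs(xyz * (100 / yref), viewing)
  }

  if (achromatic) {
    cc <- matrix(0, K, 2); mu <- c(0, 0)
    rad <- build_pixels(cc, mu)
  } else {
    if (spec$target_shares[["lightness"]] < 0.05)
      stop("unreachable target_shares: the shading model always leaves a ",
           "non-trivial lightness share")
    St <- chromatic_cov_structure(spec$target_shares, spec$chromatic_axis_deg)
    # initial guess: chromatic covariance sized against a typical
    # lightness variance; mean offset toward yellow-green
    Cc <- St * (150 / spec$target_shares[["lightness"]])
    mu <- if (is.na(spec$target_chroma_lightness)) c(-3.4, 9.4) else
      10 * (spec$target_chroma_lightness / 0.25) * c(cos(110 * pi / 180),
                                                     sin(110 * pi / 180))
    rad <- NULL
    u <- NULL
    for (it in 1:10) {
      # nominal (pre-clipping) amplitude caps: gamut clipping attenuates
      # realized chroma roughly threefold, so these are generous in UCS
      # terms; genuine unreachability is caught by the realized check below
      if (sqrt(max(eigen(Cc, symmetric = TRUE)$values)) >
          60 * spec$gamut_scale || sqrt(sum(mu^2)) > 90 * spec$gamut_scale)
        stop("unreachable target_shares for the given gamut_scale")
      cc <- z %*% t(chol(Cc))
      rad <- build_pixels(cc, mu)
      u <- probe_ucs(rad)
      realized <- variance_partition(u)
      r <- chroma_lightness_ratio(u, "median")
      if (max(abs(realized - spec$target_shares)) < 0.03 &&
          (is.na(spec$target_chroma_lightness) ||
           abs(r - spec$target_chroma_lightness) < 0.02))
        break
      vJ <- stats::var(u$J)
      Cr <- stats::cov(cbind(u$a, u$b))
      Ct <- St * (vJ / spec$target_shares[["lightness"]])
      B <- mat_sqrt(Ct) %*% solve(mat_sqrt(Cr))
      # damped update: gamut clipping saturates the response at large
      # chroma, and full-strength corrections can oscillate there
      B <- diag(2) + 0.7 * (B - diag(2))
      Cc <- B %*% Cc %*% t(B)
      Cc <- (Cc + t(Cc)) / 2
      if (!is.na(spec$target_chroma_lightness))
        mu <- mu * min(max(spec$target_chroma_lightness / max(r, 1e-6),
                           0.7), 1.5)
    }
    realized <- variance_partition(u)
    if (max(abs(realized - spec$target_shares)) > 0.06)
      stop("unreachable target_shares for the given gamut_scale ",
           sprintf("(realized %.2f/%.2f/%.2f)", realized[1], realized[2],
                   realized[3]))
  }
  cube <- array(rad, dim = c(spec$height, spec$width, length(wl)))
  spectral_image(cube, wl,
                 list(scene_id = sprintf("synthetic-%d", spec$seed),
                      landcover = spec$landcover, source = "generate_scene",
                      material_counts = tabulate(mat_idx, K)))
}

#' Generate an approximately uniform reflectance palette
#'
#' Produces `n` smooth reflectances spread approximately uniformly over
#' lightness and the chromatic plane of CAM02-UCS (a cylindrical
#' low-discrepancy layout: a golden-angle spiral in chroma/hue crossed
#' with a lightness ramp). With `gamut_scale = 0` the palette degenerates
#' to an achromatic series spaced in lightness.
#'
#' @param n number of reflectances (>= 8).
#' @param gamut_scale chroma multiplier (1 targets about 25 UCS units of
#'   maximum chroma).
#' @param seed integer seed (rotates the spiral; palettes are
#'   deterministic given the seed).
#' @param wavelengths nm grid.
#' @param illuminant_cct illuminant for the colorimetric layout.
#' @return A list of reflectance [spectrum()] objects, with the
#'   generating illuminant attached as attribute `"illuminant"`.
#' @export
generate_palette <- function(n, gamut_scale = 1, seed = 1,
                             wavelengths = seq(400, 720, by = 10),
                             illuminant_cct = 6500) {
  if (n < 8) stop("need at least 8 palette entries")
  viewing <- viewing_conditions()
  illum <- daylight_spectrum(illuminant_cct, wavelengths)
  basis <- reflectance_basis(wavelengths)
  neutral <- basis[, 1] * 0.6
  P <- chromatic_preimage(basis, neutral, illum, viewing)
  gold <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  offset <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  chroma <- 25 * gamut_scale * sqrt((i - 0.5) / n)
  hue <- (i * gold + offset) %% (2 * pi)
  gl <- exp(seq(log(0.06), log(0.92), length.out = n))
  ord <- with_seed(seed + 1L, sample.int(n))  # decouple lightness from chroma
  lapply(i, function(j) {
    cc <- chroma[j] * c(cos(hue[j]), sin(hue[j]))
    chrom <- as.numeric(basis[, -1] %*% (P %*% cc))
    v <- pmin(pmax(gl[ord[j]] * pmin(pmax(neutral + chrom, 0.01), 1), 0), 1)
    s <- spectrum(wavelengths, v, kind = "reflectance")
    s
  }) -> pal
  attr(pal, "illuminant") <- illum
  pal
}

#' Radiance set of a palette under its illuminant
#'
#' Multiplies each palette reflectance by the illuminant, giving the
#' radiance spectra treated as a single scene for information
#' estimation.
#'
#' @param palette result of [generate_palette()] (or any list of
#'   reflectance [spectrum()]s).
#' @param illuminant a radiance [spectrum()]; default the palette's
#'   attached illuminant.
#' @return A [spectral_set()].
#' @export
palette_radiance_set <- function(palette, illuminant = NULL) {
  illuminant <- illuminant %||% attr(palette, "illuminant")
  if (is.null(illuminant)) stop("no illuminant supplied or attached")
  wl <- illuminant$wavelengths
  m <- t(vapply(palette, function(s) {
    if (!isTRUE(all.equal(s$wavelengths, wl)))
      stop("palette and illuminant are on different grids")
    s$values * illuminant$values
  }, numeric(length(wl))))
  spectral_set(m, wl, provenance = list(scene_id = "palette"))
}
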
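#' CIE 1931 2-degree color-matching functions (analytic approximation)
#'
#' Evaluates the multi-lobe piecewise-Gaussian fits of Wyman, Sloan and
#' Shirley (2013) to the CIE 1931 2-degree standard observer. The fits
#' agree with the tabulated observer to within about one percent of peak,
#' which is ample for scene chromaticity statistics; they are used here in
#' place of the tabulated values so the package carries no copied data
#' tables.
#'
#' @param wavelengths numeric vector, nm.
#' @return A `length(wavelengths) x 3` matrix with columns `x`, `y`, `z`.
#' @export
cie1931_cmf <- function(wavelengths) {
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-0.5 * ((x - mu) / s)^2)
  }
  l <- as.numeric(wavelengths)
  xbar <- 1.056 * g(l, 599.8, 37.9, 31.0) +
          0.362 * g(l, 442.0, 16.0, 26.7) -
          0.065 * g(l, 501.1, 20.4, 26.2)
  ybar <- 0.821 * g(l, 568.8, 46.9, 40.5) +
          0.286 * g(l, 530.9, 16.3, 31.1)
  zbar <- 1.217 * g(l, 437.0, 11.8, 36.0) +
          0.681 * g(l, 459.0, 26.0, 13.8)
  m <- cbind(x = pmax(xbar, 0), y = pmax(ybar, 0), z = pmax(zbar, 0))
  rownames(m) <- NULL
  m
}

#' Tristimulus values of radiance spectra
#'
#' Integrates radiance against the CIE 1931 2-degree color-matching
#' functions by the trapezoid rule on the spectrum's own grid. Accepts a
#' single [spectrum()] or a matrix of spectra (rows) with an explicit
#' wavelength grid.
#'
#' @param x a radiance [spectrum()], or an `n x bands` matrix.
#' @param wavelengths required when `x` is a matrix.
#' @return For a single spectrum, a named length-3 vector `(X, Y, Z)`;
#'   for a matrix, an `n x 3` matrix. Units are arbitrary (linear in the
#'   radiance units supplied).
#' @export
spectrum_to_xyz <- function(x, wavelengths = NULL) {
  if (inherits(x, "spectrum")) {
    if (x$kind != "radiance")
      stop("spectrum_to_xyz expects a radiance spectrum")
    wavelengths <- x$wavelengths
    x <- matrix(x$values, nrow = 1)
    single <- TRUE
  } else {
    if (is.null(wavelengths))
      stop("wavelengths must be supplied for matrix input")
    x <- as.matrix(x)
    single <- FALSE
  }
  if (min(wavelengths) > 400 + 1e-9 || max(wavelengths) < 700 - 1e-9)
    stop("wavelength grid must cover 400-700 nm")
  w <- trapezoid_weights(wavelengths)
  cmf <- cie1931_cmf(wavelengths)
  out <- x %*% (cmf * w)
  colnames(out) <- c("X", "Y", "Z")
  if (single) out[1, ] else out
}

# chromaticity coordinates from tristimulus rows
xyz_to_xy <- function(xyz) {
  xyz <- rbind(xyz)
  s <- rowSums(xyz)
  cbind(x = xyz[, 1] / s, y = xyz[, 2] / s)
}

# (x, y, Y) -> XYZ
xyy_to_xyz <- function(x, y, Y) {
  cbind(X = x * Y / y, Y = Y, Z = (1 - x - y) * Y / y)
}

#' CIE daylight-locus chromaticity for a correlated color temperature
#'
#' The published CIE daylight-locus polynomials: `x_D` as a cubic in
#' `1/T` (with a coefficient switch at 7000 K) and
#' `y_D = -3 x_D^2 + 2.87 x_D - 0.275`.
#'
#' @param cct correlated color temperature, kelvin, in \[4000, 25000\].
#' @return Named vector `(x, y)`.
#' @export
daylight_chromaticity <- function(cct) {
  if (cct < 4000 || cct > 25000)
    stop("daylight series is defined for 4000-25000 K")
  t1 <- 1e3 / cct; t2 <- t1^2; t3 <- t1^3
  x <- if (cct <= 7000) {
    -4.6070 * t3 + 2.9678 * t2 + 0.09911 * t1 + 0.244063
  } else {
    -2.0064 * t3 + 1.9018 * t2 + 0.24748 * t1 + 0.237040
  }
  y <- -3.000 * x^2 + 2.870 * x - 0.275
  c(x = x, y = y)
}

# Planck blackbody spectral radiance (relative), lambda in nm
planck_radiance <- function(wavelengths, temp) {
  l <- wavelengths * 1e-9
  c2 <- 1.4388e-2  # second radiation constant, m K
  l^-5 / (exp(c2 / (l * temp)) - 1)
}

#' Daylight illuminant spectrum
#'
#' Produces a smooth daylight-like relative spectral power distribution
#' whose chromaticity lies on the CIE daylight locus for the requested
#' correlated color temperature. The spectrum is constructed as a
#' Planckian radiator at `cct` multiplied by a quadratic polynomial in
#' wavelength whose coefficients are solved (a 2 x 3 null-space problem
#' on the tristimulus constraints) so that the chromaticity equals
#' `daylight_chromaticity(cct)` exactly; it is then normalized to 100 at
#' 560 nm, the usual convention for daylight illuminants. This analytic
#' construction replaces the tabulated daylight eigenvector components,
#' which are not shipped with the package.
#'
#' @param cct correlated color temperature, kelvin, in \[4000, 25000\].
#' @param wavelengths target grid, nm (default 400-720 at 10 nm).
#' @return A radiance [spectrum()] on `wavelengths`, relative power
#'   normalized to 100 at 560 nm.
#' @export
daylight_spectrum <- function(cct, wavelengths = seq(400, 720, by = 10)) {
  xy <- daylight_chromaticity(cct)
  # solve on a fine internal grid so the result is grid-independent
  fine <- seq(380, 780, by = 1)
  base <- planck_radiance(fine, cct)
  base <- base / max(base)
  u <- (fine - 560) / 200
  B <- cbind(base, base * u, base * u^2)
  tris <- crossprod(B, cie1931_cmf(fine) * trapezoid_weights(fine))  # 3 x 3
  r1 <- tris[, 1] - xy["x"] * rowSums(tris)
  r2 <- tris[, 2] - xy["y"] * rowSums(tris)
  cf <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  spd_fine <- as.numeric(B %*% cf)
  if (spd_fine[fine == 560] < 0) spd_fine <- -spd_fine
  if (any(spd_fine < 0))
    stop("daylight construction failed to stay positive; cct out of range?")
  vals <- stats::approx(fine, spd_fine, xout = wavelengths)$y
  at560 <- stats::approx(fine, spd_fine, xout = 560)$y
  spectrum(wavelengths, 100 * vals / at560, kind = "radiance")
}
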
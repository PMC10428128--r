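# CIECAM02 forward model and the CAM02-UCS (J', a'_M, b'_M) transform.
# Matrices and constants follow CIE 159:2004 and Luo, Cui & Li (2006).

.M_CAT02 <- matrix(c(0.7328, 0.4296, -0.1624,
                     -0.7036, 1.6975, 0.0061,
                     0.0030, 0.0136, 0.9834),
                   nrow = 3, byrow = TRUE)
.M_HPE <- matrix(c(0.38971, 0.68898, -0.07868,
                   -0.22981, 1.18340, 0.04641,
                   0.00000, 0.00000, 1.00000),
                 nrow = 3, byrow = TRUE)
.M_CAT02_INV <- solve(.M_CAT02)

#' Viewing conditions for the CIECAM02 appearance model
#'
#' The defaults are ordinary CIECAM02 practice for surface colors under
#' daylight: a 6500 K daylight white, adapting luminance 64 cd/m^2,
#' background luminance factor 20, average surround, and full chromatic
#' adaptation (the illuminant is discounted, D = 1). The source analysis
#' does not pin these down; they are exposed so every descriptor can be
#' recomputed under other assumptions.
#'
#' @param white_xy chromaticity (x, y) of the adapting white; default the
#'   daylight locus point for `white_cct`.
#' @param white_cct correlated color temperature used when `white_xy` is
#'   not given, kelvin.
#' @param la adapting luminance, cd/m^2.
#' @param yb background luminance factor (percent of white).
#' @param surround `"average"`, `"dim"` or `"dark"`.
#' @param discount_illuminant if `TRUE` (default) use full adaptation
#'   D = 1; otherwise D follows the CIECAM02 formula.
#' @return An object of class `"viewing_conditions"` with all derived
#'   model constants precomputed.
#' @export
viewing_conditions <- function(white_xy = NULL, white_cct = 6500,
                               la = 64, yb = 20,
                               surround = c("average", "dim", "dark"),
                               discount_illuminant = TRUE) {
  surround <- match.arg(surround)
  if (la <= 0 || yb <= 0) stop("luminances must be positive")
  if (is.null(white_xy)) white_xy <- daylight_chromaticity(white_cct)
  sp <- switch(surround,
               average = c(F = 1.0, c = 0.69, Nc = 1.0),
               dim = c(F = 0.9, c = 0.59, Nc = 0.9),
               dark = c(F = 0.8, c = 0.525, Nc = 0.8))
  white_xyz <- drop(xyy_to_xyz(white_xy[1], white_xy[2], 100))
  k <- 1 / (5 * la + 1)
  fl <- 0.2 * k^4 * (5 * la) + 0.1 * (1 - k^4)^2 * (5 * la)^(1 / 3)
  n <- yb / 100
  nbb <- 0.725 * (1 / n)^0.2
  z <- 1.48 + sqrt(n)
  d <- if (discount_illuminant) 1 else {
    min(1, max(0, sp["F"] * (1 - (1 / 3.6) * exp(-(la + 42) / 92))))
  }
  rgb_w <- drop(.M_CAT02 %*% white_xyz)
  d_rgb <- 100 * d / rgb_w + 1 - d
  rgb_wc <- rgb_w * d_rgb
  rgb_wp <- drop(.M_HPE %*% .M_CAT02_INV %*% rgb_wc)
  rgb_wa <- cam02_response(rgb_wp, fl)
  aw <- (2 * rgb_wa[1] + rgb_wa[2] + rgb_wa[3] / 20 - 0.305) * nbb
  structure(list(white_xy = c(x = unname(white_xy[1]), y = unname(white_xy[2])),
                 white_xyz = white_xyz, la = la, yb = yb,
                 surround = surround, F = unname(sp["F"]),
                 c = unname(sp["c"]), Nc = unname(sp["Nc"]),
                 fl = fl, n = n, nbb = nbb, ncb = nbb, z = z, d = unname(d),
                 d_rgb = d_rgb, aw = aw),
            class = "viewing_conditions")
}

#' @export
print.viewing_conditions <- function(x, ...) {
  cat(sprintf(paste0("<viewing_conditions: white (%.4f, %.4f), LA %g cd/m2, ",
                     "Yb %g, %s surround, D = %.3f>\n"),
              x$white_xy[1], x$white_xy[2], x$la, x$yb, x$surround, x$d))
  invisible(x)
}

# post-adaptation nonlinear compression, sign-symmetric
cam02_response <- function(rgb, fl) {
  x <- fl * abs(rgb) / 100
  sign(rgb) * 400 * x^0.42 / (27.13 + x^0.42) + 0.1
}

#' Map tristimulus values into CAM02-UCS
#'
#' Runs the CIECAM02 forward model under `viewing` and applies the
#' CAM02-UCS transform, returning the lightness J', redness-greenness
#' a'_M, and yellowness-blueness b'_M coordinates. Input luminance is on
#' the model's 0-100 scale (the adapting white has Y = 100).
#'
#' @param xyz length-3 vector or `n x 3` matrix of tristimulus values.
#' @param viewing a [viewing_conditions()] object.
#' @return A data.frame with columns `J`, `a`, `b` (and attribute
#'   `"flagged"` counting samples with negative tristimulus input, which
#'   are clamped to zero before the model).
#' @export
xyz_to_cam02ucs <- function(xyz, viewing = viewing_conditions()) {
  stopifnot(inherits(viewing, "viewing_conditions"))
  xyz <- rbind(xyz)
  flagged <- sum(xyz < 0)
  if (flagged > 0) xyz[xyz < 0] <- 0
  rgb <- xyz %*% t(.M_CAT02)
  rgb_c <- sweep(rgb, 2, viewing$d_rgb, `*`)
  rgb_p <- rgb_c %*% t(.M_HPE %*% .M_CAT02_INV)
  rgb_a <- cam02_response(rgb_p, viewing$fl)
  ra <- rgb_a[, 1]; ga <- rgb_a[, 2]; ba <- rgb_a[, 3]
  a <- ra - 12 * ga / 11 + ba / 11
  b <- (ra + ga - 2 * ba) / 9
  h <- (atan2(b, a) * 180 / pi) %% 360
  A <- (2 * ra + ga + ba / 20 - 0.305) * viewing$nbb
  J <- 100 * (pmax(A, 0) / viewing$aw)^(viewing$c * viewing$z)
  et <- 0.25 * (cos(h * pi / 180 + 2) + 3.8)
  t <- (50000 / 13) * viewing$Nc * viewing$ncb * et * sqrt(a^2 + b^2) /
    (ra + ga + 21 / 20 * ba)
  C <- t^0.9 * sqrt(J / 100) * (1.64 - 0.29^viewing$n)^0.73
  M <- C * viewing$fl^0.25
  # CAM02-UCS (KL = 1, c1 = 0.007, c2 = 0.0228)
  Jp <- (1 + 100 * 0.007) * J / (1 + 0.007 * J)
  Mp <- log(1 + 0.0228 * M) / 0.0228
  out <- data.frame(J = Jp, a = Mp * cos(h * pi / 180),
                    b = Mp * sin(h * pi / 180))
  attr(out, "flagged") <- flagged
  attr(out, "cam") <- data.frame(J_cam = J, C = C, M = M, h = h)
  out
}

#' CAM02-UCS coordinates of all pixels of a scene
#'
#' Converts a spectral image (or set) to tristimulus values, scales
#' luminance so that the scene's near-white (the 99th percentile of Y)
#' maps to the adapting white's Y = 100, and applies
#' [xyz_to_cam02ucs()]. The hyperspectral sets carry no absolute
#' photometric calibration, so anchoring the near-white to the adapting
#' white is the package's normalization; it is stated here because all
#' lightness statistics inherit it.
#'
#' @param x a [spectral_image()] or [spectral_set()].
#' @param viewing a [viewing_conditions()] object.
#' @param max_pixels if the image has more pixels, a deterministic
#'   regular subsample of this size is used.
#' @return Data.frame of `J`, `a`, `b`, one row per (sub)pixel.
#' @export
scene_ucs <- function(x, viewing = viewing_conditions(), max_pixels = 20000) {
  m <- if (inherits(x, "spectral_image")) pixel_matrix(x)
       else if (inherits(x, "spectral_set")) x$spectra
       else stop("x must be a spectral_image or spectral_set")
  wl <- x$wavelengths
  if (nrow(m) > max_pixels) {
    idx <- round(seq(1, nrow(m), length.out = max_pixels))
    m <- m[idx, , drop = FALSE]
  }
  xyz <- spectrum_to_xyz(m, wl)
  yref <- stats::quantile(xyz[, 2], 0.99, names = FALSE)
  if (yref <= 0) stop("scene has no positive luminance")
  xyz_to_cam02ucs(xyz * (100 / yref), viewing)
}
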
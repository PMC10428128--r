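# Cone spectral sensitivities: synthetic template-based fundamentals,
# pigment shifting on a log-wavelength scale, and named observers.

#' Visual-pigment template sensitivity
#'
#' Govardovskii et al. (2000) A1 pigment template (alpha band plus beta
#' band) evaluated at the given wavelengths for a pigment peaking at
#' `lambda_max`. Used to construct the package's synthetic stand-ins for
#' measured corneal cone fundamentals: the template peaks are placed
#' directly at the corneal peak wavelengths, and no separate lens or
#' macular filtering is modelled.
#'
#' @param wavelengths nm.
#' @param lambda_max peak wavelength, nm.
#' @return Numeric vector of sensitivities, peak-normalized to 1.
#' @export
pigment_template <- function(wavelengths, lambda_max) {
  x <- lambda_max / wavelengths
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max
  bb <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((wavelengths - lmb) / bb)^2)
  s <- alpha + beta
  s / max(s)
}

# peak wavelength by monotone spline interpolation onto a 0.1-nm grid
refined_peak <- function(wavelengths, sensitivity) {
  fine <- seq(min(wavelengths), max(wavelengths), by = 0.1)
  sf <- stats::spline(wavelengths, sensitivity, xout = fine,
                      method = "natural")$y
  fine[which.max(sf)]
}

#' Cone fundamental container
#'
#' A corneal spectral sensitivity on a wavelength grid, peak-normalized
#' to 1, with its peak wavelength `lambda_max` located on a 0.1-nm
#' interpolated grid.
#'
#' @param wavelengths nm, strictly increasing.
#' @param sensitivity non-negative sensitivities.
#' @param class_name cone class label: `"L"`, `"M"` or `"S"`.
#' @return Object of class `"cone_fundamental"`.
#' @export
cone_fundamental <- function(wavelengths, sensitivity, class_name = "L") {
  check_wavelengths(wavelengths)
  sensitivity <- as.numeric(sensitivity)
  if (length(sensitivity) != length(wavelengths))
    stop("lengths differ")
  if (any(sensitivity < 0)) stop("sensitivity must be non-negative")
  sensitivity <- sensitivity / max(sensitivity)
  structure(list(wavelengths = as.numeric(wavelengths),
                 sensitivity = sensitivity,
                 lambda_max = refined_peak(wavelengths, sensitivity),
                 class_name = class_name),
            class = "cone_fundamental")
}

#' @export
print.cone_fundamental <- function(x, ...) {
  cat(sprintf("<cone_fundamental %s: peak %.1f nm, %d bands>\n",
              x$class_name, x$lambda_max, length(x$wavelengths)))
  invisible(x)
}

#' Table of the package's synthetic cone fundamentals
#'
#' Builds the long-format table (wavelength_nm, class, sensitivity) of
#' template-based L, M and S corneal sensitivities peaking at 559, 530
#' and 426 nm. The same table ships as
#' `inst/extdata/cone_fundamentals_synthetic.csv`.
#'
#' @param wavelengths nm grid (default 390-780 at 1 nm).
#' @param peaks named vector of peak wavelengths.
#' @return Data.frame with columns `wavelength_nm`, `class`,
#'   `sensitivity`.
#' @export
cone_fundamental_table <- function(wavelengths = seq(390, 780, by = 1),
                                   peaks = c(L = 559, M = 530, S = 426)) {
  do.call(rbind, lapply(names(peaks), function(cl) {
    data.frame(wavelength_nm = wavelengths, class = cl,
               sensitivity = pigment_template(wavelengths, peaks[[cl]]))
  }))
}

#' Load L, M, S cone fundamentals from a fixture table
#'
#' @param table data.frame with columns `wavelength_nm`, `class`
#'   (`"L"`, `"M"`, `"S"`) and `sensitivity`, or a path to such a CSV.
#'   Default: the synthetic fixture shipped with the package.
#' @return Named list of three [cone_fundamental()] objects `L`, `M`, `S`.
#' @export
load_fundamentals <- function(table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "cone_fundamentals_synthetic.csv",
                        package = "conegain")
    table <- if (nzchar(path)) utils::read.csv(path) else cone_fundamental_table()
  } else if (is.character(table)) {
    table <- utils::read.csv(table)
  }
  stopifnot(all(c("wavelength_nm", "class", "sensitivity") %in% names(table)))
  out <- lapply(c(L = "L", M = "M", S = "S"), function(cl) {
    t <- table[table$class == cl, ]
    if (nrow(t) == 0) stop("missing cone class ", cl)
    if (min(t$wavelength_nm) > 400 || max(t$wavelength_nm) < 720)
      stop("fundamentals must cover at least 400-720 nm")
    cone_fundamental(t$wavelength_nm, t$sensitivity, cl)
  })
  out
}

# quadratic loess smooth of sensitivity on log wavelength; span by
# 10-fold cross-validation over a fixed grid (documented in the vignette)
smooth_template <- function(fundamental,
                            spans = c(0.08, 0.12, 0.18, 0.25, 0.35)) {
  df <- data.frame(lx = log(fundamental$wavelengths),
                   y = fundamental$sensitivity)
  n <- nrow(df)
  folds <- rep_len(1:10, n)  # deterministic interleaved folds
  cv <- vapply(spans, function(sp) {
    err <- 0
    for (f in 1:10) {
      tr <- folds != f
      fit <- suppressWarnings(
        stats::loess(y ~ lx, data = df[tr, ], span = sp, degree = 2,
                     control = stats::loess.control(surface = "direct")))
      pred <- suppressWarnings(stats::predict(fit, df[!tr, ]))
      err <- err + sum((df$y[!tr] - pred)^2, na.rm = TRUE)
    }
    err
  }, numeric(1))
  sp <- spans[which.min(cv)]
  fit <- suppressWarnings(
    stats::loess(y ~ lx, data = df, span = sp, degree = 2,
                 control = stats::loess.control(surface = "direct")))
  list(fit = fit, span = sp)
}

#' Spectrally shift a cone pigment template
#'
#' Derives a hybrid pigment from a normal one by translating its
#' quadratic-loess-smoothed sensitivity along the log-wavelength axis so
#' that the peak lands at `target_peak`. The loess bandwidth is chosen by
#' cross-validation. Zero shift returns the smoothed template itself.
#'
#' @param fundamental a [cone_fundamental()].
#' @param target_peak desired peak wavelength, nm; at most 35 nm from the
#'   source peak.
#' @return A [cone_fundamental()] peaking within 1 nm of `target_peak`,
#'   with attribute `"span"` recording the loess bandwidth used.
#' @export
shift_pigment <- function(fundamental, target_peak) {
  stopifnot(inherits(fundamental, "cone_fundamental"))
  if (abs(target_peak - fundamental$lambda_max) > 35)
    stop("shift larger than 35 nm not supported")
  # a previously shifted pigment carries its smooth base: further shifts
  # translate the original smoothed template, so +delta then -delta
  # composes exactly
  base <- attr(fundamental, "smooth_base")
  if (is.null(base)) {
    sm <- smooth_template(fundamental)
    base <- list(fit = sm$fit, span = sm$span,
                 peak = fundamental$lambda_max)
  }
  sm <- base
  delta <- log(target_peak / base$peak)
  wl <- fundamental$wavelengths
  # evaluate the smoothed template at log(lambda) - delta
  lx_src <- log(wl) - delta
  rng <- range(log(wl))
  if (min(lx_src) < rng[1] - 1e-12 || max(lx_src) > rng[2] + 1e-12) {
    # clamp to template support: extrapolate flat at the tails, where the
    # template is effectively zero
    lx_src <- pmin(pmax(lx_src, rng[1]), rng[2])
  }
  vals <- suppressWarnings(stats::predict(sm$fit, data.frame(lx = lx_src)))
  vals[!is.finite(vals)] <- 0
  vals <- pmax(vals, 0)
  out <- cone_fundamental(wl, vals, fundamental$class_name)
  attr(out, "span") <- sm$span
  attr(out, "smooth_base") <- base
  out
}

#' Construct a named observer
#'
#' Observer types follow the study's pigment-peak assignments: normal
#' trichromat L(559)/M(530)/S(426); protanope missing L; deuteranope
#' missing M; protanomal with normal M(530) plus a hybrid shifted to
#' 536 nm in the L slot; deuteranomal with normal L(559) plus a hybrid
#' shifted to 549 nm in the M slot; and single-pigment M- and L-cone
#' monochromats. The S pigment is unaltered in all red-green deficiencies.
#'
#' @param name observer name: one of `"normal"`, `"protanope"`,
#'   `"deuteranope"`, `"protanomal"`, `"deuteranomal"`,
#'   `"m_monochromat"`, `"l_monochromat"`.
#' @param fundamentals list of L, M, S [cone_fundamental()]s (default:
#'   the shipped synthetic set).
#' @return Object of class `"observer"`: `name` plus an ordered list of
#'   cones, each carrying the Weber class (`"L"`, `"M"`, `"S"`) used for
#'   noise scaling.
#' @export
make_observer <- function(name = c("normal", "protanope", "deuteranope",
                                   "protanomal", "deuteranomal",
                                   "m_monochromat", "l_monochromat"),
                          fundamentals = load_fundamentals()) {
  name <- match.arg(name)
  f <- fundamentals
  as_slot <- function(cone, slot) { cone$class_name <- slot; cone }
  cones <- switch(name,
    normal = list(L = f$L, M = f$M, S = f$S),
    protanope = list(M = f$M, S = f$S),
    deuteranope = list(L = f$L, S = f$S),
    # hybrids take the Weber noise class of the slot they occupy
    protanomal = list(L = as_slot(shift_pigment(f$M, 536), "L"),
                      M = f$M, S = f$S),
    deuteranomal = list(L = f$L,
                        M = as_slot(shift_pigment(f$L, 549), "M"),
                        S = f$S),
    m_monochromat = list(M = f$M),
    l_monochromat = list(L = f$L))
  structure(list(name = name, cones = cones), class = "observer")
}

#' @export
print.observer <- function(x, ...) {
  peaks <- vapply(x$cones, function(c) c$lambda_max, numeric(1))
  cat(sprintf("<observer %s: %d cone class(es), peaks %s nm>\n", x$name,
              length(x$cones), paste(sprintf("%.0f", peaks), collapse = "/")))
  invisible(x)
}
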
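# Cone excitations q = integral of L(lambda) S(lambda) d lambda, and
# Weber-scaled Gaussian cone noise.

#' Weber-scaled cone noise model
#'
#' Phototransduction noise is modelled as Gaussian with standard
#' deviation proportional to the local cone excitation. The constant of
#' proportionality (Weber fraction) is quoted for L cones; M and S cones
#' scale by the ratios of the psychophysical increment-threshold Weber
#' fractions 0.018, 0.019 and 0.087 for L, M and S. The headline level is
#' `weber_l = 0.02`, a practical minimum; 0.01 and 0.05 are the other
#' levels the analysis sweeps.
#'
#' @param weber_l relative SD for L cones (> 0).
#' @param weber_ratios multipliers for the other classes relative to L.
#' @return Object of class `"noise_model"`.
#' @export
noise_model <- function(weber_l = 0.02,
                        weber_ratios = c(L = 1, M = 0.019 / 0.018,
                                         S = 0.087 / 0.018)) {
  if (weber_l <= 0) stop("weber_l must be positive")
  if (any(weber_ratios <= 0)) stop("weber ratios must be positive")
  stopifnot(all(c("L", "M", "S") %in% names(weber_ratios)))
  structure(list(weber_l = weber_l, weber_ratios = weber_ratios),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  w <- x$weber_l * x$weber_ratios
  cat(sprintf("<noise_model: relative SD L %.4f, M %.4f, S %.4f>\n",
              w["L"], w["M"], w["S"]))
  invisible(x)
}

# per-cone Weber fractions for an observer under a noise model
observer_webers <- function(observer, noise) {
  vapply(observer$cones, function(cone) {
    noise$weber_l * noise$weber_ratios[[cone$class_name]]
  }, numeric(1))
}

#' Noiseless cone excitations of a set of spectra
#'
#' Trapezoid-rule quadrature of each radiance spectrum against each of
#' the observer's corneal sensitivities. Both the spectra (assumed
#' smooth between bands) and the fundamentals are interpolated by
#' natural cubic splines onto a common 1-nm grid before integration, so
#' the quadrature matches a fine-grid reference within a fraction of a
#' percent even from a 10-nm band spacing. Since spline interpolation is
#' linear in the data, the whole operation reduces to one fixed
#' `bands x cones` quadrature matrix.
#'
#' @param spectra a [spectral_set()] or [spectral_image()].
#' @param observer an [make_observer()] object.
#' @return `n x c` matrix of non-negative excitations, columns named by
#'   cone slot.
#' @export
cone_excitations <- function(spectra, observer) {
  stopifnot(inherits(observer, "observer"))
  if (inherits(spectra, "spectral_image")) spectra <- as_spectral_set(spectra)
  stopifnot(inherits(spectra, "spectral_set"))
  wl <- spectra$wavelengths
  fine <- seq(min(wl), max(wl), by = 1)
  # spline interpolation matrix from the band grid to the fine grid
  W <- vapply(seq_along(wl), function(j) {
    e <- numeric(length(wl)); e[j] <- 1
    stats::spline(wl, e, xout = fine, method = "natural")$y
  }, numeric(length(fine)))
  S <- vapply(observer$cones, function(cone) {
    if (min(cone$wavelengths) > min(wl) || max(cone$wavelengths) < max(wl))
      stop("fundamental does not cover the scene wavelength grid")
    pmax(stats::spline(cone$wavelengths, cone$sensitivity, xout = fine,
                       method = "natural")$y, 0)
  }, numeric(length(fine)))
  M <- crossprod(W, S * trapezoid_weights(fine))
  q <- spectra$spectra %*% M
  colnames(q) <- names(observer$cones)
  pmax(q, 0)
}

#' Add Weber-scaled Gaussian noise to cone excitations
#'
#' `y = q (1 + w_c e)`, with `e` standard normal, independent per sample
#' and cone class, and `w_c` the class Weber fraction. An excitation of
#' zero therefore stays exactly zero.
#'
#' @param excitations `n x c` matrix from [cone_excitations()].
#' @param observer the observer the columns belong to (fixes each
#'   column's Weber class).
#' @param noise a [noise_model()].
#' @param seed integer; the draw is deterministic given the seed.
#' @return Matrix of noisy excitations, same shape as `excitations`.
#' @export
add_cone_noise <- function(excitations, observer, noise = noise_model(),
                           seed = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(excitations < 0)) stop("excitations must be non-negative")
  w <- observer_webers(observer, noise)
  if (length(w) != ncol(excitations))
    stop("observer cone count does not match excitation columns")
  with_seed(seed, {
    eps <- matrix(stats::rnorm(length(excitations)),
                  nrow = nrow(excitations))
    excitations * (1 + sweep(eps, 2, w, `*`))
  })
}

#' Paired radiance/excitation sample for information estimation
#'
#' Bundles the mutual-information variables: `x`, the sampled radiance
#' vectors, and `y`, the corresponding noisy cone excitations of an
#' observer.
#'
#' @param x `n x bands` radiance matrix.
#' @param y `n x c` noisy excitation matrix.
#' @param observer_name label.
#' @param weber_l noise level used.
#' @return Object of class `"excitation_sample"`.
#' @export
excitation_sample <- function(x, y, observer_name, weber_l) {
  if (nrow(x) != nrow(y)) stop("x and y must be paired (same row count)")
  if (!ncol(y) %in% 1:3) stop("y must have 1-3 cone columns")
  structure(list(x = x, y = y, observer_name = observer_name,
                 weber_l = weber_l),
            class = "excitation_sample")
}
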
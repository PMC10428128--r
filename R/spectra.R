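#' Spectral data containers
#'
#' `spectrum()` holds a single spectral function on a wavelength grid,
#' either a radiance (power per area per solid angle per nm, arbitrary
#' linear units) or a dimensionless reflectance in \[0, 1\].
#' `spectral_image()` holds a height x width x bands radiance cube
#' \eqn{L(u, v; \lambda)}, and `spectral_set()` a plain n x bands matrix of
#' spectra detached from spatial layout, with provenance.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param values for `spectrum()`, a numeric vector of the same length as
#'   `wavelengths`; for `spectral_image()`, an `h x w x b` numeric array;
#'   for `spectral_set()`, an `n x b` numeric matrix.
#' @param kind `"radiance"` or `"reflectance"`.
#' @param metadata named list; recognized entries are `scene_id`,
#'   `landcover` (`"vegetated"`, `"nonvegetated"` or `"unknown"`) and
#'   `source`.
#' @param provenance named list recording where the rows came from
#'   (e.g. `scene_id`, `pixel_index`).
#' @return An object of class `"spectrum"`, `"spectral_image"` or
#'   `"spectral_set"`.
#' @export
spectrum <- function(wavelengths, values, kind = c("radiance", "reflectance")) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  check_wavelengths(wavelengths)
  if (length(values) != length(wavelengths))
    stop("values and wavelengths must have the same length")
  if (!all(is.finite(values)))
    stop("spectrum values must be finite")
  if (kind == "reflectance" && (any(values < 0) || any(values > 1)))
    stop("reflectance values must lie in [0, 1]")
  if (kind == "radiance" && any(values < 0))
    stop("radiance values must be non-negative")
  structure(list(wavelengths = wavelengths, values = values, kind = kind),
            class = "spectrum")
}

#' @rdname spectrum
#' @export
spectral_image <- function(values, wavelengths, metadata = list()) {
  check_wavelengths(wavelengths)
  if (length(dim(values)) != 3L)
    stop("values must be a height x width x bands array")
  if (dim(values)[3] != length(wavelengths))
    stop("third array dimension must match the wavelength grid")
  if (!all(is.finite(values)))
    stop("radiance values must be finite")
  if (any(values < 0))
    stop("radiance values must be non-negative")
  metadata <- utils::modifyList(
    list(scene_id = "unnamed", landcover = "unknown", source = "memory"),
    metadata)
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 metadata = metadata),
            class = "spectral_image")
}

#' @rdname spectrum
#' @export
spectral_set <- function(values, wavelengths, provenance = list()) {
  check_wavelengths(wavelengths)
  values <- as.matrix(values)
  if (ncol(values) != length(wavelengths))
    stop("column count must match the wavelength grid")
  if (nrow(values) < 1L)
    stop("a spectral set needs at least one spectrum")
  if (!all(is.finite(values)))
    stop("spectra must be finite")
  structure(list(spectra = values, wavelengths = as.numeric(wavelengths),
                 provenance = provenance),
            class = "spectral_set")
}

check_wavelengths <- function(wavelengths) {
  if (length(wavelengths) < 2L || anyNA(wavelengths))
    stop("need at least two finite wavelengths")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  invisible(TRUE)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d bands, %g-%g nm>\n", x$kind,
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_image '%s': %d x %d px, %d bands (%g-%g nm), %s>\n",
              x$metadata$scene_id, d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths), x$metadata$landcover))
  invisible(x)
}

#' @export
print.spectral_set <- function(x, ...) {
  cat(sprintf("<spectral_set: %d spectra, %d bands (%g-%g nm)>\n",
              nrow(x$spectra), ncol(x$spectra),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectral_image <- function(x) dim(x$values)

# n x bands matrix view of all pixels (row-major over image rows)
pixel_matrix <- function(image) {
  d <- dim(image$values)
  matrix(image$values, nrow = d[1] * d[2], ncol = d[3])
}

#' Convert a spectral image to a spectral set of all its pixels
#'
#' @param image a [spectral_image()].
#' @return A [spectral_set()] whose rows are the image pixels in
#'   column-major order.
#' @export
as_spectral_set <- function(image) {
  stopifnot(inherits(image, "spectral_image"))
  spectral_set(pixel_matrix(image), image$wavelengths,
               provenance = list(scene_id = image$metadata$scene_id,
                                 pixel_index = seq_len(prod(dim(image$values)[1:2]))))
}

# trapezoid quadrature weights for a (possibly uneven) grid
trapezoid_weights <- function(wavelengths) {
  n <- length(wavelengths)
  w <- numeric(n)
  dl <- diff(wavelengths)
  w[1] <- dl[1] / 2
  w[n] <- dl[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dl[-(n - 1)] + dl[-1]) / 2
  w
}

# scoped RNG: run expr under a seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
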
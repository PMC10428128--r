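# Reading, writing, and conditioning of hyperspectral radiance images.
#
# Native on-disk formats:
#  * "envi": classic ENVI pair - a text .hdr and a flat binary cube
#    (float32, band-sequential, rows within band in line order).
#  * "ascii": a self-describing plain-text layout (header lines starting
#    with '#', then one pixel per row), used for small text fixtures.
# Wavelength metadata is mandatory in both; files without it are refused
# rather than guessed.

#' Write a spectral image to disk
#'
#' @param image a [spectral_image()].
#' @param path output path. For `"envi"` this is the header path (the
#'   binary cube is written next to it with extension `.raw`); for
#'   `"ascii"` a single text file.
#' @param format `"envi"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_hyperspectral <- function(image, path, format = c("envi", "ascii")) {
  format <- match.arg(format)
  stopifnot(inherits(image, "spectral_image"))
  d <- dim(image$values)
  if (format == "envi") {
    raw_path <- sub("\\.hdr$", ".raw", path)
    if (identical(raw_path, path)) raw_path <- paste0(path, ".raw")
    hdr <- c("ENVI",
             sprintf("description = {conegain scene %s}", image$metadata$scene_id),
             sprintf("samples = %d", d[2]),
             sprintf("lines = %d", d[1]),
             sprintf("bands = %d", d[3]),
             "header offset = 0",
             "file type = ENVI Standard",
             "data type = 4",
             "interleave = bsq",
             "byte order = 0",
             sprintf("scene id = %s", image$metadata$scene_id),
             sprintf("landcover = %s", image$metadata$landcover),
             sprintf("wavelength units = Nanometers"),
             sprintf("wavelength = { %s }",
                     paste(format(image$wavelengths, trim = TRUE),
                           collapse = ", ")))
    writeLines(hdr, path)
    con <- file(raw_path, "wb")
    on.exit(close(con))
    # bsq: band-major, line-major within band
    v <- aperm(image$values, c(2, 1, 3))  # samples, lines, bands
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# conegain-ascii 1",
                 sprintf("# dims %d %d %d", d[1], d[2], d[3]),
                 sprintf("# scene_id %s", image$metadata$scene_id),
                 sprintf("# landcover %s", image$metadata$landcover),
                 sprintf("# wavelengths_nm %s",
                         paste(format(image$wavelengths, trim = TRUE),
                               collapse = " "))), con)
    utils::write.table(pixel_matrix(image), con, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a hyperspectral radiance image
#'
#' @param path file path: an ENVI header (`.hdr`) or a conegain ascii
#'   file.
#' @param format_hint `"auto"`, `"envi"` or `"ascii"`.
#' @return A [spectral_image()] with wavelengths taken from file
#'   metadata. Missing or non-monotone wavelength metadata is a fatal
#'   error; no resampling is applied.
#' @export
read_hyperspectral <- function(path, format_hint = c("auto", "envi", "ascii")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format_hint == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    format_hint <- if (identical(first, "ENVI")) "envi"
                   else if (grepl("^# conegain-ascii", first)) "ascii"
                   else stop("unknown format: ", path)
  }
  if (format_hint == "envi") {
    hdr <- readLines(path, warn = FALSE)
    getf <- function(key) {
      ln <- grep(paste0("^", key, "\\s*="), hdr, value = TRUE)
      if (length(ln) == 0) return(NULL)
      trimws(sub("^[^=]*=", "", ln[1]))
    }
    samples <- as.integer(getf("samples")); lines_ <- as.integer(getf("lines"))
    bands <- as.integer(getf("bands"))
    dtype <- as.integer(getf("data type"))
    interleave <- tolower(getf("interleave"))
    if (is.null(getf("wavelength")))
      stop("wavelength metadata missing; refusing to guess")
    wl_start <- grep("^wavelength\\s*=", hdr)
    wl_txt <- paste(hdr[wl_start:length(hdr)], collapse = " ")
    wl_txt <- sub(".*\\{", "", wl_txt); wl_txt <- sub("\\}.*", "", wl_txt)
    wavelengths <- as.numeric(strsplit(wl_txt, ",")[[1]])
    if (anyNA(wavelengths) || length(wavelengths) != bands)
      stop("malformed wavelength list")
    if (any(diff(wavelengths) <= 0))
      stop("wavelengths must be strictly increasing")
    if (!identical(dtype, 4L)) stop("only float32 (data type 4) supported")
    if (!identical(interleave, "bsq")) stop("only bsq interleave supported")
    raw_path <- sub("\\.hdr$", ".raw", path)
    if (identical(raw_path, path)) raw_path <- paste0(path, ".raw")
    n <- samples * lines_ * bands
    v <- readBin(raw_path, "numeric", n = n, size = 4, endian = "little")
    if (length(v) != n) stop("binary cube truncated")
    cube <- aperm(array(v, dim = c(samples, lines_, bands)), c(2, 1, 3))
    meta <- list(scene_id = getf("scene id") %||% basename(path),
                 landcover = getf("landcover") %||% "unknown",
                 source = path)
    spectral_image(cube, wavelengths, meta)
  } else {
    ln <- readLines(path, warn = FALSE)
    hdr <- ln[startsWith(ln, "#")]
    geth <- function(key) {
      x <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
      if (length(x) == 0) return(NULL)
      sub(paste0("^# ", key, " "), "", x[1])
    }
    dims <- as.integer(strsplit(geth("dims"), " ")[[1]])
    wl <- geth("wavelengths_nm")
    if (is.null(wl)) stop("wavelength metadata missing; refusing to guess")
    wavelengths <- as.numeric(strsplit(trimws(wl), "\\s+")[[1]])
    if (any(diff(wavelengths) <= 0))
      stop("wavelengths must be strictly increasing")
    m <- as.matrix(utils::read.table(text = ln[!startsWith(ln, "#")]))
    cube <- array(m, dim = dims)
    spectral_image(cube, wavelengths,
                   list(scene_id = geth("scene_id") %||% basename(path),
                        landcover = geth("landcover") %||% "unknown",
                        source = path))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a spectral image onto a new wavelength grid
#'
#' Linear interpolation per pixel onto `grid`, e.g. the 400-700 nm at
#' 10 nm grid (31 bands) used for the wider-range image set.
#' Extrapolation outside the source range is refused.
#'
#' @param image a [spectral_image()].
#' @param grid target wavelengths, nm, within the source range.
#' @return A [spectral_image()] on `grid`.
#' @export
resample_wavelengths <- function(image, grid) {
  check_wavelengths(grid)
  wl <- image$wavelengths
  if (min(grid) < min(wl) || max(grid) > max(wl))
    stop("target grid requires extrapolation outside the source range")
  if (isTRUE(all.equal(as.numeric(grid), wl))) return(image)
  d <- dim(image$values)
  m <- pixel_matrix(image)
  out <- t(apply(m, 1, function(s) stats::approx(wl, s, xout = grid)$y))
  spectral_image(array(out, dim = c(d[1], d[2], length(grid))), grid,
                 image$metadata)
}

#' Spatially downsample by 2 x 2 block averaging
#'
#' Each output spectrum is the mean of its 2 x 2 pixel block; a trailing
#' odd row or column is dropped. Used to reduce pixel-pixel correlations
#' and non-imaging noise before sampling.
#'
#' @param image a [spectral_image()] with height and width at least 2.
#' @return A [spectral_image()] of dimensions `floor(h/2) x floor(w/2)`.
#' @export
downsample_2x2 <- function(image) {
  d <- dim(image$values)
  if (d[1] < 2 || d[2] < 2) stop("image must be at least 2 x 2")
  h2 <- d[1] %/% 2; w2 <- d[2] %/% 2
  v <- image$values[seq_len(2 * h2), seq_len(2 * w2), , drop = FALSE]
  out <- (v[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE] +
          v[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE] +
          v[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE] +
          v[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE]) / 4
  spectral_image(out, image$wavelengths, image$metadata)
}

#' Subtract an estimated dark-noise offset
#'
#' `values = max(values - offset, 0)` per band. An offset exceeding the
#' 99th percentile of any band is treated as suspicious and refused
#' unless `force = TRUE`.
#'
#' @param image a [spectral_image()].
#' @param offset_estimate per-band non-negative offsets (recycled if
#'   scalar), or `"auto"` for the per-band 0.1 percentile.
#' @param force proceed even when the offset looks too large.
#' @return The corrected [spectral_image()]; the number of clipped values
#'   is reported via `message()` when positive.
#' @export
subtract_dark_offset <- function(image, offset_estimate = "auto",
                                 force = FALSE) {
  d <- dim(image$values)
  m <- pixel_matrix(image)
  if (identical(offset_estimate, "auto")) {
    offset <- apply(m, 2, stats::quantile, probs = 0.001, names = FALSE)
  } else {
    offset <- rep_len(as.numeric(offset_estimate), d[3])
  }
  if (any(offset < 0)) stop("offset must be non-negative")
  q99 <- apply(m, 2, stats::quantile, probs = 0.99, names = FALSE)
  if (any(offset > q99) && !force)
    stop("offset exceeds the 99th percentile of a band; use force = TRUE ",
         "if this is intended")
  out <- sweep(m, 2, offset, `-`)
  clipped <- sum(out < 0)
  if (clipped > 0)
    message(sprintf("subtract_dark_offset: clipped %d negative values", clipped))
  out[out < 0] <- 0
  spectral_image(array(out, dim = d), image$wavelengths, image$metadata)
}

#' Randomly sample pixel spectra from an image
#'
#' Uniform random pixel draw, by default with replacement (the image is
#' treated as a sample from a continuous radiance distribution);
#' without-replacement mode is available when `n` does not exceed the
#' pixel count.
#'
#' @param image a [spectral_image()].
#' @param n number of spectra (the study uses 1e4 per image).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param replace sample with replacement (default `TRUE`).
#' @return A [spectral_set()] whose provenance records the pixel indices.
#' @export
sample_spectra <- function(image, n, seed = NULL, replace = TRUE) {
  if (n <= 0) stop("n must be positive")
  m <- pixel_matrix(image)
  if (!replace && n > nrow(m))
    stop("n exceeds pixel count for without-replacement sampling")
  idx <- with_seed(seed, sample.int(nrow(m), n, replace = replace))
  spectral_set(m[idx, , drop = FALSE], image$wavelengths,
               provenance = list(scene_id = image$metadata$scene_id,
                                 pixel_index = idx))
}

#' Remove the upper half of a scene
#'
#' Keeps the lower `ceiling(h/2)` rows (row 1 is the top of the image),
#' the control used to exclude sky.
#'
#' @param image a [spectral_image()] with at least 2 rows.
#' @return The cropped [spectral_image()].
#' @export
crop_upper_half <- function(image) {
  h <- dim(image$values)[1]
  if (h < 2) stop("image must have at least 2 rows")
  keep <- (h - ceiling(h / 2) + 1):h
  spectral_image(image$values[keep, , , drop = FALSE], image$wavelengths,
                 image$metadata)
}
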
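# Sup-metric thinning toward approximately uniform surface frequencies,
# and gamut-maximizing unions across scenes.

#' Sup-metric distance between two spectra
#'
#' `d(l_r, l_s) = sup over lambda of |l_r(lambda) - l_s(lambda)|` on a
#' shared wavelength grid.
#'
#' @param s1,s2 [spectrum()] objects or plain numeric vectors on the same
#'   grid.
#' @return Non-negative distance.
#' @export
sup_distance <- function(s1, s2) {
  v1 <- if (inherits(s1, "spectrum")) s1$values else as.numeric(s1)
  v2 <- if (inherits(s2, "spectrum")) s2$values else as.numeric(s2)
  if (inherits(s1, "spectrum") && inherits(s2, "spectrum") &&
      !isTRUE(all.equal(s1$wavelengths, s2$wavelengths)))
    stop("spectra are on different wavelength grids")
  if (length(v1) != length(v2)) stop("spectra are on different grids")
  max(abs(v1 - v2))
}

#' Thin a spectral set to a minimum sup-metric spacing
#'
#' Greedy sequential thinning: spectra are visited in a seeded random
#' order and retained iff their sup-distance to every already-retained
#' spectrum is at least `d`. Every removed spectrum therefore lies within
#' `d` of some retained one, and all retained pairs are at least `d`
#' apart. The visiting order is randomized because it changes which
#' spectra survive; results that depend on it are reported seed-averaged.
#'
#' @param set a [spectral_set()].
#' @param d sup-metric radius, `>= 0`.
#' @param order_seed integer seed for the visiting order.
#' @return Object of class `"thinning_result"`: `retained`
#'   ([spectral_set()]), `d`, `removed_count`, and (when produced by
#'   [adaptive_thin()]) a `history` data.frame.
#' @export
thin_spectra <- function(set, d, order_seed = 1) {
  stopifnot(inherits(set, "spectral_set"))
  if (d < 0) stop("d must be non-negative")
  n <- nrow(set$spectra)
  ord <- with_seed(order_seed, sample.int(n))
  keep <- if (d == 0) rep(TRUE, n) else .greedy_thin(set$spectra, d, ord)
  retained <- spectral_set(set$spectra[keep, , drop = FALSE],
                           set$wavelengths,
                           provenance = c(set$provenance,
                                          list(thinned_at = d,
                                               kept_rows = which(keep))))
  structure(list(retained = retained, d = d,
                 removed_count = sum(!keep), history = NULL),
            class = "thinning_result")
}

#' @export
print.thinning_result <- function(x, ...) {
  cat(sprintf("<thinning_result: d = %g, retained %d, removed %d>\n",
              x$d, nrow(x$retained$spectra), x$removed_count))
  invisible(x)
}

#' Adaptive thinning to the largest stable radius
#'
#' Increases the thinning radius along `d_grid`, estimating the
#' information on each retained subset with `info_fn`, and returns the
#' result at the largest radius for which (a) the retained count stays at
#' or above `count_floor` and (b) the information estimate changed by
#' less than `stability_tol` bits from the previous radius. The full
#' `(d, retained count, I)` history is recorded.
#'
#' @param set a [spectral_set()].
#' @param info_fn function taking a [spectral_set()] and returning bits.
#' @param d_grid strictly increasing radii.
#' @param stability_tol bits (default 0.05).
#' @param count_floor minimum retained count (default 500) keeping the
#'   estimator meaningful.
#' @param order_seed seed for the greedy order.
#' @return A `"thinning_result"` with `history` populated.
#' @export
adaptive_thin <- function(set, info_fn, d_grid, stability_tol = 0.05,
                          count_floor = 500, order_seed = 1) {
  if (any(diff(d_grid) <= 0)) stop("d_grid must be strictly increasing")
  history <- data.frame(d = numeric(), retained = integer(), bits = numeric())
  results <- list()
  prev_bits <- NA_real_
  best <- NULL
  for (d in d_grid) {
    res <- thin_spectra(set, d, order_seed)
    cnt <- nrow(res$retained$spectra)
    if (cnt < count_floor) {
      history <- rbind(history, data.frame(d = d, retained = cnt, bits = NA))
      break
    }
    bits <- info_fn(res$retained)
    history <- rbind(history, data.frame(d = d, retained = cnt, bits = bits))
    if (!is.na(prev_bits) && abs(bits - prev_bits) < stability_tol) best <- res
    prev_bits <- bits
  }
  if (is.null(best)) {
    # no stable step: fall back to the smallest radius meeting the floor
    ok <- history[!is.na(history$bits), ]
    if (nrow(ok) == 0) stop("no radius in d_grid meets the count floor")
    best <- thin_spectra(set, ok$d[1], order_seed)
  }
  best$history <- history
  best
}

#' Thinned union of spectra across scenes
#'
#' Concatenates already-thinned sets (gamut-maximizing union over
#' scenes) and applies [thin_spectra()] once more at radius `d`.
#'
#' @param thinned_sets list of [spectral_set()]s on a shared grid.
#' @param d sup-metric radius for the final thinning.
#' @param order_seed seed for the greedy order.
#' @return A `"thinning_result"`.
#' @export
union_gamut <- function(thinned_sets, d, order_seed = 1) {
  stopifnot(length(thinned_sets) >= 1)
  wl <- thinned_sets[[1]]$wavelengths
  for (s in thinned_sets)
    if (!isTRUE(all.equal(s$wavelengths, wl)))
      stop("sets are on different wavelength grids")
  all_spectra <- do.call(rbind, lapply(thinned_sets, function(s) s$spectra))
  ids <- unlist(lapply(seq_along(thinned_sets), function(i) {
    sid <- thinned_sets[[i]]$provenance$scene_id %||% as.character(i)
    rep(sid, nrow(thinned_sets[[i]]$spectra))
  }))
  thin_spectra(spectral_set(all_spectra, wl,
                            provenance = list(scene_id = ids)),
               d, order_seed)
}
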
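# Mutual information between scene radiance spectra and noisy cone
# excitations, via Kozachenko-Leonenko k-nearest-neighbour differential
# entropies with a small-sample offset correction.

#' Kozachenko-Leonenko differential entropy
#'
#' kNN estimate of the differential entropy of a continuous sample, in
#' bits:
#' `h = d * mean(log2 r_k) + log2 V_d + (psi(n) - psi(k)) / ln 2`,
#' where `r_k` are kth-nearest-neighbour Euclidean distances and `V_d`
#' the unit-ball volume. Duplicate points make `r_k = 0`; they are broken
#' by a deterministic additive jitter at 1e-9 of the coordinate scale
#' (reported via `message()`).
#'
#' @param samples `n x d` numeric matrix (a vector is treated as 1-D).
#' @param k neighbour order, `1 <= k < n`.
#' @return Entropy in bits.
#' @export
kl_entropy <- function(samples, k = 3) {
  x <- as.matrix(samples)
  n <- nrow(x); d <- ncol(x)
  if (k < 1 || k >= n) stop("need 1 <= k < n")
  if (d >= n) stop("dimension must be below the sample count")
  if (anyDuplicated(x)) {
    message("kl_entropy: duplicate points; applying 1e-9-scale jitter")
    scale <- max(apply(x, 2, function(v) diff(range(v))), 1)
    x <- x + with_seed(0L, matrix(stats::runif(n * d, -1, 1), n, d)) *
      (1e-9 * scale)
  }
  r <- .knn_kth_dist(x, as.integer(k))
  if (any(r == 0)) stop("duplicates beyond jitter tolerance")
  log2_vd <- (d / 2 * log(pi) - lgamma(d / 2 + 1)) / log(2)
  d * mean(log2(r)) + log2_vd + (digamma(n) - digamma(k)) / log(2)
}

# core MI at a fixed sample: h(X) + h(Y) - h(X, Y), same k throughout
mi_core <- function(x, y, k) {
  kl_entropy(x, k) + kl_entropy(y, k) - kl_entropy(cbind(x, y), k)
}

# small-sample offset: evaluate the estimator at the full sample, at the
# two disjoint halves (averaged), and at the four disjoint quarters
# (averaged), then extrapolate linearly in 1/n with weights
# proportional to size. Block averaging keeps the variance of each curve
# point near that of the full-sample estimate, so the extrapolation adds
# little noise.
offset_extrapolate <- function(est_fn, n, min_size, seed = NULL) {
  with_seed(seed, {
    full <- est_fn(seq_len(n))
    h <- floor(n / 2); q <- floor(n / 4)
    if (h < min_size) return(full)
    perm <- sample.int(n)
    halves <- mean(vapply(0:1, function(i) {
      est_fn(perm[(i * h + 1):((i + 1) * h)])
    }, numeric(1)))
    if (q >= min_size) {
      quarters <- mean(vapply(0:3, function(i) {
        est_fn(perm[(i * q + 1):((i + 1) * q)])
      }, numeric(1)))
      sizes <- c(n, h, q)
      vals <- c(full, halves, quarters)
      fit <- stats::lm(vals ~ I(1 / sizes), weights = sizes)
      unname(stats::coef(fit)[1])
    } else {
      # two sizes: exact linear extrapolation to 1/n -> 0
      full + (full - halves) * (1 / n) / (1 / h - 1 / n)
    }
  })
}

drop_constant_cols <- function(m) {
  sds <- apply(m, 2, stats::sd)
  m[, sds > 0, drop = FALSE]
}

#' Mutual information by the offset Kozachenko-Leonenko estimator
#'
#' Estimates `I(X; Y) = h(X) + h(Y) - h(X, Y)` with [kl_entropy()].
#' Coordinates of X and Y are each standardized to unit variance first
#' (mutual information is invariant to marginal rescaling, and
#' standardization stabilizes kNN distances in high dimension). With
#' `offset = TRUE`, the estimator's finite-sample error is removed by a
#' matched-Gaussian offset: the same estimator, at the same `n` and `k`,
#' is run on `surrogates` Gaussian samples with the data's joint
#' covariance, whose true mutual information is known in closed form,
#' and its mean error is subtracted. This cancels the bias shared by
#' data and surrogate (it is exact in distribution for Gaussian data)
#' without the noise amplification of extrapolation schemes. The spread
#' `se_bits` comes from re-estimating on `se_reps` random half-samples.
#'
#' @param x `n x dx` matrix (or vector) of the first variable.
#' @param y `n x dy` matrix (or vector), paired with `x` by row.
#' @param k neighbour order (default 3).
#' @param offset apply the matched-Gaussian offset (default `TRUE`).
#' @param se_reps number of half-sample resamples for `se_bits`
#'   (0 skips; `se_bits` is then `NA`).
#' @param seed integer seed controlling the surrogate draws and
#'   resampling.
#' @param surrogates number of Gaussian surrogate samples averaged for
#'   the offset.
#' @return Object of class `"mi_estimate"`: `bits`, `se_bits`, `n`, `k`,
#'   `offset_applied`.
#' @export
kl_mutual_information <- function(x, y, k = 3, offset = TRUE, se_reps = 4,
                                  seed = NULL, surrogates = 3) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must be paired")
  n <- nrow(x)
  if (n < 50) stop("need at least 50 paired samples")
  x <- drop_constant_cols(x); y <- drop_constant_cols(y)
  if (ncol(x) == 0 || ncol(y) == 0) {
    warning("degenerate (constant) variable; mutual information is 0")
    return(new_mi_estimate(0, 0, n, k, offset))
  }
  x <- scale(x); y <- scale(y)
  est <- mi_core(x, y, k)
  if (offset) {
    dx <- ncol(x)
    C <- stats::cov(cbind(x, y)) + diag(1e-10, dx + ncol(y))
    i_gauss <- 0.5 * log2(det(C[1:dx, 1:dx, drop = FALSE]) *
                          det(C[-(1:dx), -(1:dx), drop = FALSE]) / det(C))
    L <- chol(C)
    err <- with_seed(seed, mean(vapply(seq_len(surrogates), function(b) {
      z <- matrix(stats::rnorm(n * ncol(C)), n) %*% L
      mi_core(z[, 1:dx, drop = FALSE], z[, -(1:dx), drop = FALSE], k) -
        i_gauss
    }, numeric(1))))
    est <- est - err
  }
  se <- NA_real_
  if (se_reps > 0) {
    half <- floor(n / 2)
    reps <- vapply(seq_len(se_reps), function(r) {
      idx <- with_seed(if (is.null(seed)) NULL else seed + r,
                       sample.int(n, half))
      mi_core(x[idx, , drop = FALSE], y[idx, , drop = FALSE], k)
    }, numeric(1))
    se <- stats::sd(reps) / sqrt(2)  # variance roughly proportional to 1/n
  }
  new_mi_estimate(est, se, n, k, offset)
}

new_mi_estimate <- function(bits, se, n, k, offset, extra = list()) {
  structure(c(list(bits = bits, se_bits = se, n = n, k = k,
                   offset_applied = offset), extra),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate: %.3f bits (se %.3f), n = %d, k = %d%s%s>\n",
              x$bits, x$se_bits, x$n, x$k,
              if (x$offset_applied) ", offset" else "",
              if (!is.null(x$observer)) paste0(", ", x$observer) else ""))
  invisible(x)
}

# draw the shared LMS noise field and the paired sample once; reused by
# scene_information and information_loss so reference and deficient
# estimates see identical pixels and noise
scene_sample <- function(x, n, seed) {
  if (inherits(x, "spectral_image")) {
    # without replacement when the image is large enough: repeated pixels
    # are exact duplicates in X and would lean on the jitter contract
    npix <- prod(dim(x$values)[1:2])
    sample_spectra(x, min(n, npix), seed = seed, replace = n > npix)
  } else if (inherits(x, "spectral_set")) {
    x  # palettes and thinned sets: use all available spectra
  } else stop("x must be a spectral_image or spectral_set")
}

noise_field <- function(n, seed) {
  with_seed(seed, matrix(stats::rnorm(n * 3), n, 3,
                         dimnames = list(NULL, c("L", "M", "S"))))
}

apply_noise_field <- function(q, observer, noise, eps) {
  w <- observer_webers(observer, noise)
  slots <- vapply(observer$cones, function(c) c$class_name, character(1))
  q * (1 + sweep(eps[, slots, drop = FALSE], 2, w, `*`))
}

# Plug-in information for the known Weber-Gaussian channel:
# I = h(Y) - h(Y | q), with h(Y | q) analytic for the multiplicative
# Gaussian noise and h(Y) evaluated as a Monte-Carlo average of the exact
# mixture output density over the sampled source. Estimates the
# information of the empirical source distribution; the 1/n subsample
# extrapolation removes most of the finite-source bias.
channel_information <- function(q, y, webers, offset = TRUE, se_reps = 4,
                                seed = NULL) {
  n <- nrow(q)
  if (any(q <= 0))
    stop("channel estimator requires strictly positive excitations")
  sdq <- sweep(q, 2, webers, `*`)
  i_at <- function(idx) {
    logf <- .mix_logdensity(q[idx, , drop = FALSE], sdq[idx, , drop = FALSE],
                            y[idx, , drop = FALSE])
    h_y <- -mean(logf) / log(2)
    h_cond <- sum(0.5 * log2(2 * pi * exp(1)) + log2(webers)) +
      sum(colMeans(log2(q[idx, , drop = FALSE])))
    h_y - h_cond
  }
  est <- if (offset) {
    offset_extrapolate(i_at, n, min_size = 100, seed = seed)
  } else {
    i_at(seq_len(n))
  }
  se <- NA_real_
  if (se_reps > 0) {
    half <- floor(n / 2)
    reps <- vapply(seq_len(se_reps), function(r) {
      idx <- with_seed(if (is.null(seed)) NULL else seed + 17L * r,
                       sample.int(n, half))
      i_at(idx)
    }, numeric(1))
    se <- stats::sd(reps) / sqrt(2)
  }
  list(bits = est, se = se)
}

#' Information available from a scene to an observer
#'
#' Draws `n` pixel spectra (all spectra for a [spectral_set()], e.g. a
#' palette or thinned subset), computes noiseless cone excitations,
#' applies Weber-scaled cone noise, and estimates the mutual information
#' between radiance vectors X and noisy excitations Y with the offset
#' Kozachenko-Leonenko estimator.
#'
#' @param x a [spectral_image()] or [spectral_set()].
#' @param observer an [make_observer()] observer (or a name).
#' @param noise a [noise_model()].
#' @param n pixels to sample from an image (study default 1e4).
#' @param seed integer; controls the pixel draw, the noise field and the
#'   estimator's subsampling.
#' @param k neighbour order (`method = "knn"` only).
#' @param se_reps half-sample resamples for the spread.
#' @param method `"channel"` (default) evaluates `I = h(Y) - h(Y|q)`
#'   with the analytically known Weber-Gaussian channel density, needing
#'   only a Monte-Carlo average of the exact mixture output density;
#'   `"knn"` is the generic route, estimating I between the raw radiance
#'   vectors and Y with [kl_mutual_information()]. The two agree where
#'   the generic estimator is reliable (weak dependence, low dimension);
#'   on strongly dependent scene data the channel form is far more
#'   accurate (see the methods vignette).
#' @return An `"mi_estimate"` with `observer` and `weber_l` fields.
#' @export
scene_information <- function(x, observer = "normal", noise = noise_model(),
                              n = 10000, seed = 1, k = 3, se_reps = 4,
                              method = c("channel", "knn")) {
  method <- match.arg(method)
  if (is.character(observer)) observer <- make_observer(observer)
  ss <- scene_sample(x, n, seed)
  m <- nrow(ss$spectra)
  q <- cone_excitations(ss, observer)
  eps <- noise_field(m, seed + 1L)
  y <- apply_noise_field(q, observer, noise, eps)
  if (method == "channel") {
    w <- observer_webers(observer, noise)
    est <- channel_information(q, y, w, offset = TRUE, se_reps = se_reps,
                               seed = seed + 2L)
    new_mi_estimate(est$bits, est$se, m, NA_integer_, TRUE,
                    extra = list(observer = observer$name,
                                 weber_l = noise$weber_l,
                                 method = method))
  } else {
    est <- kl_mutual_information(ss$spectra, y, k = k, offset = TRUE,
                                 se_reps = se_reps, seed = seed + 2L)
    new_mi_estimate(est$bits, est$se_bits, est$n, est$k, TRUE,
                    extra = list(observer = observer$name,
                                 weber_l = noise$weber_l,
                                 method = method))
  }
}

#' Information loss under color vision deficiency
#'
#' Paired estimate of `DeltaI = I - I'`: the information available to the
#' reference (normal trichromatic) observer minus that available to the
#' deficient observer, computed on the same sampled pixels and the same
#' underlying L/M/S noise field. Also reports the percentage reduction in
#' the effective number of distinguishable surfaces,
#' `100 (1 - 2^-DeltaI)`.
#'
#' @param x a [spectral_image()] or [spectral_set()].
#' @param deficient_observer deficient observer (or name).
#' @param noise a [noise_model()].
#' @param n pixels to sample from an image.
#' @param seed integer seed shared by both estimates.
#' @param k neighbour order.
#' @param se_reps half-sample resamples.
#' @param reference_observer the comparison observer (default normal).
#' @param method estimator route, as in [scene_information()].
#' @return Object of class `"delta_i"`: `bits`, `reference_bits`,
#'   `deficient_bits`, `observer`, `percent_surface_reduction`,
#'   `se_bits` (conservative: the two spreads added in quadrature).
#' @export
information_loss <- function(x, deficient_observer, noise = noise_model(),
                             n = 10000, seed = 1, k = 3, se_reps = 4,
                             reference_observer = "normal",
                             method = c("channel", "knn")) {
  method <- match.arg(method)
  if (is.character(deficient_observer))
    deficient_observer <- make_observer(deficient_observer)
  if (is.character(reference_observer))
    reference_observer <- make_observer(reference_observer)
  ss <- scene_sample(x, n, seed)
  m <- nrow(ss$spectra)
  eps <- noise_field(m, seed + 1L)
  est_one <- function(obs) {
    q <- cone_excitations(ss, obs)
    y <- apply_noise_field(q, obs, noise, eps)
    if (method == "channel") {
      w <- observer_webers(obs, noise)
      e <- channel_information(q, y, w, offset = TRUE, se_reps = se_reps,
                               seed = seed + 2L)
      list(bits = e$bits, se_bits = e$se, n = m)
    } else {
      kl_mutual_information(ss$spectra, y, k = k, offset = TRUE,
                            se_reps = se_reps, seed = seed + 2L)
    }
  }
  ref <- est_one(reference_observer)
  def <- if (identical(deficient_observer$name, reference_observer$name))
    ref else est_one(deficient_observer)
  se <- sqrt(sum(c(ref$se_bits, def$se_bits)^2, na.rm = TRUE))
  structure(list(bits = ref$bits - def$bits,
                 reference_bits = ref$bits,
                 deficient_bits = def$bits,
                 observer = deficient_observer$name,
                 weber_l = noise$weber_l,
                 percent_surface_reduction =
                   100 * (1 - 2^(-(ref$bits - def$bits))),
                 se_bits = se, n = ref$n, k = k),
            class = "delta_i")
}

#' @export
print.delta_i <- function(x, ...) {
  cat(sprintf(paste0("<delta_i %s: %.3f bits (se %.3f) of %.3f; ",
                     "%.1f%% fewer distinguishable surfaces>\n"),
              x$observer, x$bits, x$se_bits, x$reference_bits,
              x$percent_surface_reduction))
  invisible(x)
}

#' Effective number of distinguishable surfaces
#'
#' `N = 2^I`, the effective alphabet size: the number of surfaces
#' distinguishable through the noisy cone responses, accounting for their
#' unequal frequencies of occurrence.
#'
#' @param bits information in bits, non-negative.
#' @return `2^bits`.
#' @export
effective_surfaces <- function(bits) {
  if (any(bits < 0)) stop("information must be non-negative")
  2^bits
}

#' Resampling stability report for an information estimate
#'
#' Re-estimates information on random pixel subsets at several subset
#' fractions and reports the spread at each size, flagging instability
#' when the spread at the largest size exceeds `threshold`.
#'
#' @param estimate_fn function taking a [spectral_set()] and returning a
#'   numeric estimate in bits.
#' @param image a [spectral_image()].
#' @param subset_fracs fractions of `n_base` to test.
#' @param reps resamples per fraction (at least 10).
#' @param seed integer seed.
#' @param n_base pixel count at fraction 1.
#' @param threshold spread (SD, bits) above which the largest size is
#'   flagged unstable.
#' @return Object of class `"stability_report"`: data.frame `table`
#'   (fraction, n, mean, sd) and logical `stable`.
#' @export
stability_check <- function(estimate_fn, image,
                            subset_fracs = c(0.25, 0.5, 1), reps = 10,
                            seed = 1, n_base = 2000, threshold = 0.1) {
  if (reps < 10) stop("need at least 10 reps")
  rows <- lapply(subset_fracs, function(f) {
    n <- max(100, round(f * n_base))
    vals <- vapply(seq_len(reps), function(r) {
      ss <- sample_spectra(image, n, seed = seed + 1000L * r + round(1e6 * f))
      estimate_fn(ss)
    }, numeric(1))
    data.frame(fraction = f, n = n, mean = mean(vals), sd = stats::sd(vals))
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 stable = tab$sd[which.max(tab$n)] <= threshold,
                 threshold = threshold),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report: %s (threshold %.2f bits)>\n",
              if (x$stable) "stable" else "UNSTABLE", x$threshold))
  print(x$table, row.names = FALSE)
  invisible(x)
}
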
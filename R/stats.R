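# Percentile-bootstrap confidence intervals, the logit transform, and
# ordinary plus linear-circular regression with axial-data handling.

#' Efron percentile bootstrap confidence interval
#'
#' Resamples the data with replacement `reps` times, applies
#' `statistic_fn` to each resample, and returns the 2.5th and 97.5th
#' percentiles of the bootstrap distribution (nonparametric mode: no
#' assumptions about the statistic's sampling distribution).
#'
#' @param samples numeric vector, or data.frame resampled by row
#'   (case resampling).
#' @param statistic_fn function of a resample returning one number.
#' @param reps bootstrap replications (default 1000, minimum 100).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return Object of class `"bootstrap_ci"`: `point_estimate`, `lo`,
#'   `hi`, `reps`.
#' @export
percentile_bootstrap_ci <- function(samples, statistic_fn = mean,
                                    reps = 1000, seed = 1, level = 0.95) {
  n <- if (is.data.frame(samples)) nrow(samples) else length(samples)
  if (n < 5) stop("need at least 5 samples")
  if (reps < 100) stop("need at least 100 replications")
  pick <- if (is.data.frame(samples)) {
    function(idx) samples[idx, , drop = FALSE]
  } else {
    function(idx) samples[idx]
  }
  boots <- with_seed(seed, vapply(seq_len(reps), function(r) {
    statistic_fn(pick(sample.int(n, n, replace = TRUE)))
  }, numeric(1)))
  a <- (1 - level) / 2
  qs <- stats::quantile(boots, c(a, 1 - a), names = FALSE, type = 6)
  structure(list(point_estimate = statistic_fn(samples),
                 lo = qs[1], hi = qs[2], reps = reps, level = level),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci: %.4g (%.0f%% CI %.4g to %.4g, %d reps)>\n",
              x$point_estimate, 100 * x$level, x$lo, x$hi, x$reps))
  invisible(x)
}

#' Logit transform of a proportion
#'
#' `ln(p / (1 - p))`. Boundary values 0 and 1 are refused: any clamping
#' is an explicit data edit that belongs with the caller.
#'
#' @param p proportions strictly inside (0, 1).
#' @return Log-odds.
#' @export
logit <- function(p) {
  if (any(p <= 0 | p >= 1))
    stop("logit requires 0 < p < 1; clamp explicitly if needed")
  log(p / (1 - p))
}

#' Linear regression with a bootstrap gradient interval
#'
#' Ordinary least squares of `y` on `x`, with a percentile-bootstrap
#' 95% confidence interval for the gradient obtained by case resampling.
#'
#' @param x,y numeric vectors, at least 3 points.
#' @param reps bootstrap replications.
#' @param seed integer seed.
#' @return Object of class `"lin_fit"`: `intercept`, `gradient`,
#'   `gradient_ci` (lo, hi), `r_squared`, `n`.
#' @export
linear_regression <- function(x, y, reps = 1000, seed = 1) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 paired points")
  if (stats::sd(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  ci <- percentile_bootstrap_ci(
    data.frame(x = x, y = y),
    function(d) unname(stats::coef(stats::lm(y ~ x, data = d))[2]),
    reps = reps, seed = seed)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 gradient = unname(stats::coef(fit)[2]),
                 gradient_ci = c(lo = ci$lo, hi = ci$hi),
                 r_squared = summary(fit)$r.squared,
                 n = length(x)),
            class = "lin_fit")
}

#' @export
print.lin_fit <- function(x, ...) {
  cat(sprintf("<lin_fit: gradient %.3f (CI %.3f to %.3f), R2 = %.2f, n = %d>\n",
              x$gradient, x$gradient_ci["lo"], x$gradient_ci["hi"],
              x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.lin_fit <- function(object, ...) {
  c(intercept = object$intercept, gradient = object$gradient)
}

#' Linear-circular regression on axial directions
#'
#' Regression of `y` on an axial direction (defined modulo 180 degrees):
#' angles are doubled to the full circle, `y` is regressed on the cosine
#' and sine of the doubled angle, and the fitted extremum directions are
#' folded back to the axial range. The fitted model is
#' `y = b0 + bc cos(2 theta) + bs sin(2 theta)`, whose maximum lies at
#' `theta = atan2(bs, bc) / 2` (mod 180) and minimum 90 degrees away.
#'
#' @param angles_axial_deg directions in degrees in \[0, 180).
#' @param y response, same length, at least 4 points.
#' @return Object of class `"circular_fit"`: `intercept`, `cos_coef`,
#'   `sin_coef`, `r_squared`, `extremum_dirs` (named `max`, `min`,
#'   degrees in \[0, 180)), `amplitude`, and `circular_mean_dir` of the
#'   angle sample.
#' @export
circular_linear_regression <- function(angles_axial_deg, y) {
  th <- angles_axial_deg %% 180
  if (length(th) != length(y) || length(th) < 4)
    stop("need at least 4 paired points")
  dbl <- 2 * th * pi / 180
  cx <- cos(dbl); sx <- sin(dbl)
  if (stats::sd(cx) < 1e-12 && stats::sd(sx) < 1e-12)
    stop("collinear design: angles carry no axial variation")
  fit <- stats::lm(y ~ cx + sx)
  b <- stats::coef(fit)
  bc <- unname(b["cx"]); bs <- unname(b["sx"])
  if (is.na(bc)) bc <- 0
  if (is.na(bs)) bs <- 0
  max_dir <- (atan2(bs, bc) * 180 / pi / 2) %% 180
  mean_dir <- (atan2(mean(sx), mean(cx)) * 180 / pi / 2) %% 180
  structure(list(intercept = unname(b[1]), cos_coef = bc, sin_coef = bs,
                 r_squared = summary(fit)$r.squared,
                 amplitude = sqrt(bc^2 + bs^2),
                 extremum_dirs = c(max = max_dir,
                                   min = (max_dir + 90) %% 180),
                 circular_mean_dir = mean_dir,
                 n = length(y)),
            class = "circular_fit")
}

#' @export
print.circular_fit <- function(x, ...) {
  cat(sprintf(paste0("<circular_fit: max at %.1f deg, min at %.1f deg, ",
                     "amplitude %.3f, R2 = %.2f, n = %d>\n"),
              x$extremum_dirs["max"], x$extremum_dirs["min"],
              x$amplitude, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.circular_fit <- function(object, ...) {
  c(intercept = object$intercept, cos_coef = object$cos_coef,
    sin_coef = object$sin_coef)
}

#' @export
predict.circular_fit <- function(object, angles_axial_deg, ...) {
  dbl <- 2 * (angles_axial_deg %% 180) * pi / 180
  object$intercept + object$cos_coef * cos(dbl) + object$sin_coef * sin(dbl)
}
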
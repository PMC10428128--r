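# Scene color descriptors in CAM02-UCS, and dichromatic confusion-axis
# directions. These quantities describe scenes; by design they never feed
# the information estimates (see the vignette).

#' Partition of CAM02-UCS variance into lightness and chromatic shares
#'
#' Fractions of the total variance of (J', a'_M, b'_M) points carried by
#' each coordinate: `var J' / (var J' + var a' + var b')` and likewise for
#' the two chromatic axes.
#'
#' @param points data.frame with columns `J`, `a`, `b` (e.g. from
#'   [scene_ucs()]).
#' @return Named numeric vector `(lightness, rg, yb)` summing to 1.
#' @export
variance_partition <- function(points) {
  stopifnot(all(c("J", "a", "b") %in% names(points)))
  if (nrow(points) < 2) stop("need at least two points")
  v <- c(lightness = stats::var(points$J),
         rg = stats::var(points$a),
         yb = stats::var(points$b))
  tot <- sum(v)
  if (tot <= 0) stop("zero total variance: degenerate point set")
  v / tot
}

#' Mean ratio of chroma to lightness
#'
#' Mean over points of `sqrt(a'^2 + b'^2) / J'`, the colorfulness measure
#' used to characterize how much color a scene contains.
#'
#' @inheritParams variance_partition
#' @param summary `"mean"` or `"median"`.
#' @return A single non-negative number.
#' @export
chroma_lightness_ratio <- function(points, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  if (any(points$J <= 0)) stop("all points must have J > 0")
  r <- sqrt(points$a^2 + points$b^2) / points$J
  if (summary == "mean") mean(r) else stats::median(r)
}

#' Major chromatic axis of a scene
#'
#' Direction of most variance of the (a'_M, b'_M) distribution, from the
#' leading eigenvector of its 2 x 2 covariance, folded to the axial range
#' \[0, 180) degrees, anticlockwise from the redness-greenness axis a'_M.
#'
#' @inheritParams variance_partition
#' @return Object of class `"chromatic_axis"`: list with `phi` (degrees in
#'   \[0, 180)) and `variance_explained` (leading-eigenvalue fraction of
#'   chromatic variance, in \[0.5, 1\]).
#' @export
major_chromatic_axis <- function(points) {
  if (nrow(points) < 3) stop("need at least three points")
  S <- stats::cov(cbind(points$a, points$b))
  if (sum(diag(S)) <= 0) stop("no chromatic variance: axis undefined")
  e <- eigen(S, symmetric = TRUE)
  if ((e$values[1] - e$values[2]) / sum(e$values) < 1e-9)
    stop("isotropic chromatic covariance: axis undefined")
  phi <- (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180
  structure(list(phi = phi,
                 variance_explained = e$values[1] / sum(e$values)),
            class = "chromatic_axis")
}

#' @export
print.chromatic_axis <- function(x, ...) {
  cat(sprintf("<chromatic_axis: phi = %.1f deg, %.0f%% of chromatic variance>\n",
              x$phi, 100 * x$variance_explained))
  invisible(x)
}

# copunctal points of the three dichromatic confusion-line families in
# CIE 1931 (x, y); standard literature constants
.copunctal <- list(protan = c(x = 0.747, y = 0.253),
                   deutan = c(x = 1.400, y = -0.400),
                   tritan = c(x = 0.171, y = 0.000))

#' Confusion-axis direction at the CAM02-UCS origin
#'
#' Axial direction, anticlockwise from the a'_M axis, of the dichromatic
#' confusion locus through the adapting white. The confusion line through
#' the white toward the copunctal point is constructed in the CIE 1931
#' (x, y) diagram; closely spaced points about the white are mapped at
#' fixed luminance into CAM02-UCS and the tangent direction at the origin
#' is taken by a symmetric finite difference, folded to \[0, 180)
#' degrees.
#'
#' @param type `"protan"`, `"deutan"` or `"tritan"`.
#' @param viewing a [viewing_conditions()] object; its white is the point
#'   the tangent is evaluated at.
#' @param step chromaticity half-step of the finite difference (the
#'   result is stable over at least 1e-4 to 1e-2).
#' @param orthogonal if `TRUE`, return the direction orthogonal to the
#'   confusion axis (`(phi + 90) mod 180`) instead.
#' @return Direction in degrees in \[0, 180).
#' @export
confusion_axis_direction <- function(type = c("protan", "deutan", "tritan"),
                                     viewing = viewing_conditions(),
                                     step = 1e-3, orthogonal = FALSE) {
  type <- match.arg(type)
  cp <- .copunctal[[type]]
  w <- viewing$white_xy
  dirv <- c(cp["x"] - w["x"], cp["y"] - w["y"])
  nrm <- sqrt(sum(dirv^2))
  if (nrm < 1e-9) stop("white coincides with the copunctal point")
  dirv <- dirv / nrm
  xy <- rbind(w + step * dirv, w - step * dirv)
  xyz <- xyy_to_xyz(xy[, 1], xy[, 2], viewing$yb)  # fixed luminance
  ucs <- xyz_to_cam02ucs(xyz, viewing)
  da <- ucs$a[1] - ucs$a[2]
  db <- ucs$b[1] - ucs$b[2]
  if (sqrt(da^2 + db^2) < 1e-12) stop("degenerate tangent")
  phi <- (atan2(db, da) * 180 / pi) %% 180
  if (orthogonal) phi <- (phi + 90) %% 180
  phi
}
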
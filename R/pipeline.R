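# Full-analysis orchestration over a scene collection: conditioning,
# color descriptors, information and losses per observer and noise
# level, uniform-subset and union conditions, and the summary and
# regression stages.

# bisect a thinning radius whose retained count lands in [lo, hi]
choose_thin_d <- function(set, lo = 500, hi = 1000, order_seed = 1,
                          max_iter = 25) {
  n <- nrow(set$spectra)
  if (n <= hi) return(list(d = 0, result = thin_spectra(set, 0, order_seed)))
  d_lo <- 0
  d_hi <- max(set$spectra) - min(set$spectra)  # retains ~1
  res <- NULL
  for (i in seq_len(max_iter)) {
    d <- (d_lo + d_hi) / 2
    res <- thin_spectra(set, d, order_seed)
    cnt <- nrow(res$retained$spectra)
    if (cnt >= lo && cnt <= hi) return(list(d = d, result = res))
    if (cnt > hi) d_lo <- d else d_hi <- d
  }
  list(d = d_lo, result = thin_spectra(set, d_lo, order_seed))
}

#' Run the full color-deficiency information analysis
#'
#' For each scene: computes CAM02-UCS descriptors (variance shares,
#' chroma/lightness ratio, major chromatic axis), then paired information
#' estimates I and I' for every observer and noise level under the
#' `raw` condition (random pixel sample), the `thinned` condition (the
#' sample thinned to approximately uniform frequencies, radius chosen to
#' retain 500-1000 spectra), and one collection-wide `union` condition
#' (thinned union of all scenes' thinned sets). Per-scene failures are
#' logged and excluded; the run aborts if more than 10% of scenes fail.
#'
#' @param scenes list of [spectral_image()] objects, or of
#'   [scene_spec()]s (generated on the fly).
#' @param observers deficient observer names to evaluate against the
#'   normal reference.
#' @param weber_levels numeric vector of L-cone relative noise SDs.
#' @param n pixels sampled per scene.
#' @param seed master integer seed; per-scene seeds are derived from it
#'   and recorded in the table.
#' @param conditions subset of `c("raw", "thinned", "union")`.
#' @param se_reps half-sample resamples per estimate.
#' @param method MI estimator route (see [scene_information()]).
#' @param thin_range retained-count window for the thinning radius.
#' @return Object of class `"cvd_analysis"`: `table` (one row per scene
#'   x condition x observer x weber, plus normal-reference rows),
#'   `descriptors` (one row per scene), `failed` (scene ids), and the
#'   call parameters.
#' @export
run_analysis <- function(scenes,
                         observers = c("protanope", "deuteranope",
                                       "protanomal", "deuteranomal"),
                         weber_levels = 0.02, n = 2500, seed = 1,
                         conditions = c("raw", "thinned", "union"),
                         se_reps = 2, method = c("channel", "knn"),
                         thin_range = c(500, 1000)) {
  method <- match.arg(method)
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (!length(observers)) stop("need at least one deficient observer")
  if (any(weber_levels <= 0)) stop("weber levels must be positive")
  obs_objects <- lapply(stats::setNames(nm = c("normal", observers)),
                        make_observer)
  rows <- list()
  desc_rows <- list()
  thinned_sets <- list()
  thin_ds <- numeric()
  failed <- character()

  losses_for <- function(x, scene_id, condition, scene_seed) {
    out <- list()
    for (w in weber_levels) {
      nm <- noise_model(weber_l = w)
      ref <- scene_information(x, obs_objects[["normal"]], nm, n = n,
                               seed = scene_seed, se_reps = se_reps,
                               method = method)
      out[[length(out) + 1]] <- data.frame(
        scene_id = scene_id, condition = condition, observer = "normal",
        weber = w, I_bits = ref$bits, se_bits = ref$se_bits,
        deltaI_bits = 0, pct_surfaces_lost = 0, seed = scene_seed)
      for (ob in observers) {
        dl <- information_loss(x, obs_objects[[ob]], nm, n = n,
                               seed = scene_seed, se_reps = se_reps,
                               method = method)
        out[[length(out) + 1]] <- data.frame(
          scene_id = scene_id, condition = condition, observer = ob,
          weber = w, I_bits = dl$deficient_bits, se_bits = dl$se_bits,
          deltaI_bits = dl$bits,
          pct_surfaces_lost = dl$percent_surface_reduction,
          seed = scene_seed)
      }
    }
    do.call(rbind, out)
  }

  for (i in seq_along(scenes)) {
    scene_seed <- seed + 1000L * i
    res <- tryCatch({
      img <- scenes[[i]]
      if (inherits(img, "scene_spec")) img <- generate_scene(img)
      sid <- img$metadata$scene_id
      u <- scene_ucs(img)
      shares <- variance_partition(u)
      phi <- tryCatch(major_chromatic_axis(u)$phi, error = function(e) NA)
      desc <- data.frame(scene_id = sid,
                         landcover = img$metadata$landcover,
                         share_lightness = shares[["lightness"]],
                         share_rg = shares[["rg"]],
                         share_yb = shares[["yb"]],
                         chroma_lightness = chroma_lightness_ratio(u, "median"),
                         phi = phi)
      tab <- NULL
      if ("raw" %in% conditions)
        tab <- rbind(tab, losses_for(img, sid, "raw", scene_seed))
      if (any(c("thinned", "union") %in% conditions)) {
        ss <- scene_sample(img, n, scene_seed)
        th <- choose_thin_d(ss, thin_range[1], thin_range[2],
                            order_seed = scene_seed)
        th$result$retained$provenance$scene_id <- sid
        if ("thinned" %in% conditions)
          tab <- rbind(tab, losses_for(th$result$retained, sid, "thinned",
                                       scene_seed))
        list(tab = tab, desc = desc, thinned = th$result$retained,
             d = th$d)
      } else list(tab = tab, desc = desc, thinned = NULL, d = NA)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("scene %d failed: %s", i, conditionMessage(res)))
      failed <- c(failed, as.character(i))
      next
    }
    rows[[length(rows) + 1]] <- res$tab
    desc_rows[[length(desc_rows) + 1]] <- res$desc
    if (!is.null(res$thinned)) {
      thinned_sets[[length(thinned_sets) + 1]] <- res$thinned
      thin_ds <- c(thin_ds, res$d)
    }
  }
  if (length(failed) > 0.1 * length(scenes))
    stop("more than 10% of scenes failed; aborting run")

  if ("union" %in% conditions && length(thinned_sets)) {
    d_union <- stats::median(thin_ds)
    un <- union_gamut(thinned_sets, d_union, order_seed = seed)
    rows[[length(rows) + 1]] <-
      losses_for(un$retained, "union", "union", seed + 7L)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  descriptors <- do.call(rbind, desc_rows)
  rownames(descriptors) <- NULL
  structure(list(table = table, descriptors = descriptors,
                 failed = failed, observers = observers,
                 weber_levels = weber_levels, n = n, seed = seed,
                 method = method, conditions = conditions),
            class = "cvd_analysis")
}

#' @export
print.cvd_analysis <- function(x, ...) {
  cat(sprintf(paste0("<cvd_analysis: %d scenes, observers %s, weber %s, ",
                     "%d result rows%s>\n"),
              nrow(x$descriptors), paste(x$observers, collapse = "/"),
              paste(x$weber_levels, collapse = "/"), nrow(x$table),
              if (length(x$failed)) paste0(", ", length(x$failed), " failed")
              else ""))
  invisible(x)
}

#' @export
summary.cvd_analysis <- function(object, ...) {
  summarize_losses(object)
}

#' Per-condition mean information losses with bootstrap intervals
#'
#' Group means of the estimated losses over scenes, per condition,
#' observer, and noise level, with Efron percentile-bootstrap 95%
#' intervals over scenes, plus the percentage reduction in the effective
#' number of distinguishable surfaces implied by the mean loss.
#'
#' @param x a `"cvd_analysis"` or its `table` data.frame.
#' @param reps bootstrap replications.
#' @param seed integer seed.
#' @return Data.frame with one row per (condition, observer, weber).
#' @export
summarize_losses <- function(x, reps = 1000, seed = 1) {
  tab <- if (inherits(x, "cvd_analysis")) x$table else x
  tab <- tab[tab$observer != "normal", , drop = FALSE]
  if (!nrow(tab)) stop("no deficient-observer rows to summarize")
  groups <- unique(tab[, c("condition", "observer", "weber")])
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- tab$condition == groups$condition[g] &
      tab$observer == groups$observer[g] & tab$weber == groups$weber[g]
    d <- tab$deltaI_bits[sel]
    if (length(d) >= 5) {
      ci <- percentile_bootstrap_ci(d, mean, reps = reps, seed = seed)
      lo <- ci$lo; hi <- ci$hi
    } else {
      lo <- hi <- NA_real_
    }
    data.frame(condition = groups$condition[g],
               observer = groups$observer[g], weber = groups$weber[g],
               n_scenes = length(d), mean_deltaI = mean(d),
               ci_lo = lo, ci_hi = hi,
               pct_surfaces_lost = 100 * (1 - 2^(-mean(d))))
  })
  res <- do.call(rbind, out)
  res[order(res$condition, res$observer, res$weber), ]
}

#' Regressions of information loss on scene chromatic structure
#'
#' For each observer (raw condition, one noise level): the linear
#' regression of the per-scene loss on the logit of the scene's
#' redness-greenness variance share, and the linear-circular regression
#' of the loss on the scene's major chromatic axis direction.
#'
#' @param analysis a `"cvd_analysis"` from [run_analysis()] with at
#'   least 10 scenes carrying valid shares and axes.
#' @param weber noise level to use (default the first analyzed).
#' @param reps bootstrap replications for the gradient interval.
#' @param seed integer seed.
#' @return Object of class `"cvd_regressions"`: per observer a list with
#'   `share_fit` (`"lin_fit"`) and `axis_fit` (`"circular_fit"`).
#' @export
regression_suite <- function(analysis, weber = NULL, reps = 1000, seed = 1) {
  stopifnot(inherits(analysis, "cvd_analysis"))
  weber <- weber %||% analysis$weber_levels[1]
  tab <- analysis$table
  tab <- tab[tab$condition == "raw" & tab$weber == weber &
             tab$observer != "normal", , drop = FALSE]
  d <- analysis$descriptors
  merged <- merge(tab, d, by = "scene_id")
  merged <- merged[is.finite(merged$phi) & merged$share_rg > 0 &
                   merged$share_rg < 1, , drop = FALSE]
  if (length(unique(merged$scene_id)) < 10)
    stop("need at least 10 scenes with valid descriptors")
  fits <- lapply(stats::setNames(nm = unique(merged$observer)), function(ob) {
    m <- merged[merged$observer == ob, ]
    list(share_fit = linear_regression(logit(m$share_rg), m$deltaI_bits,
                                       reps = reps, seed = seed),
         axis_fit = circular_linear_regression(m$phi, m$deltaI_bits))
  })
  structure(list(fits = fits, weber = weber, n_scenes =
                   length(unique(merged$scene_id))),
            class = "cvd_regressions")
}

#' @export
print.cvd_regressions <- function(x, ...) {
  cat(sprintf("<cvd_regressions: %d scenes, weber %g>\n", x$n_scenes,
              x$weber))
  for (ob in names(x$fits)) {
    f <- x$fits[[ob]]
    cat(sprintf(paste0("  %-13s loss ~ logit(rg share): gradient %.3f ",
                       "(CI %.3f to %.3f, R2 %.2f); ",
                       "loss ~ axis: max at %.0f deg (R2 %.2f)\n"),
                ob, f$share_fit$gradient, f$share_fit$gradient_ci["lo"],
                f$share_fit$gradient_ci["hi"], f$share_fit$r_squared,
                f$axis_fit$extremum_dirs["max"], f$axis_fit$r_squared))
  }
  invisible(x)
}

#' @export
plot.cvd_analysis <- function(x, weber = NULL, ...) {
  weber <- weber %||% x$weber_levels[1]
  tab <- x$table[x$table$observer != "normal" & x$table$weber == weber, ]
  tab$grp <- interaction(tab$condition, tab$observer, drop = TRUE)
  graphics::stripchart(deltaI_bits ~ grp, data = tab, vertical = TRUE,
                       method = "jitter", pch = 1, las = 2,
                       ylab = expression(Delta * I ~ "(bits)"),
                       main = sprintf("Information losses (weber %g)", weber),
                       ...)
  invisible(x)
}
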
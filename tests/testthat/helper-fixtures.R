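# Shared fixtures, built lazily once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small natural-like scene used across modules
small_scene <- function(seed = 1) {
  cached(paste0("scene", seed), function() {
    generate_scene(scene_spec(width = 48, height = 48, seed = seed))
  })
}

# a tiny image with hand-set values for IO arithmetic checks
tiny_image <- function() {
  wl <- seq(400, 720, by = 10)
  set.seed(11)
  vals <- array(runif(4 * 6 * length(wl), 0.1, 2), dim = c(4, 6, length(wl)))
  spectral_image(vals, wl, list(scene_id = "tiny", landcover = "vegetated"))
}

# the natural-like synthetic suite of the acceptance property criteria:
# 20 seeded scenes with shares ~ 0.8/0.07/0.13 and skewed frequencies,
# analyzed at weber 0.02; information losses cached across test files
suite_scenes <- function(n_scenes = 20) {
  cached("suite_scenes", function() {
    lapply(seq_len(n_scenes), function(s) {
      generate_scene(scene_spec(width = 72, height = 72,
                                target_shares = c(0.80, 0.07, 0.13),
                                frequency_skew = 1.2, seed = s))
    })
  })
}

suite_losses <- function() {
  cached("suite_losses", function() {
    scenes <- suite_scenes()
    observers <- c("deuteranomal", "deuteranope", "protanomal", "protanope",
                   "m_monochromat", "l_monochromat")
    obs_objects <- lapply(stats::setNames(nm = observers), make_observer)
    nm <- noise_model(weber_l = 0.02)
    rows <- lapply(seq_along(scenes), function(i) {
      do.call(rbind, lapply(observers, function(ob) {
        dl <- information_loss(scenes[[i]], obs_objects[[ob]], nm,
                               n = 2000, seed = 100 + i, se_reps = 2)
        data.frame(scene = i, observer = ob, deltaI = dl$bits,
                   se = dl$se_bits, ref_bits = dl$reference_bits)
      }))
    })
    do.call(rbind, rows)
  })
}

# exact plug-in oracle for the Weber-Gaussian channel on a spectral set:
# h(Y) from the true mixture output density over all source atoms,
# evaluated at fresh Monte-Carlo draws (independent of the estimator's
# subsample-extrapolation path)
channel_oracle <- function(set, observer, noise, n_mc = 6000, seed = 9) {
  q <- cone_excitations(set, observer)
  w <- conegain:::observer_webers(observer, noise)
  set.seed(seed)
  pick <- sample.int(nrow(q), n_mc, replace = TRUE)
  eps <- matrix(rnorm(n_mc * ncol(q)), n_mc)
  y <- q[pick, , drop = FALSE] * (1 + sweep(eps, 2, w, `*`))
  sdq <- sweep(q, 2, w, `*`)
  logf <- conegain:::.mix_logdensity(q, sdq, y)
  h_y <- -mean(logf) / log(2)
  h_cond <- sum(0.5 * log2(2 * pi * exp(1)) + log2(w)) +
    sum(colMeans(log2(q)))
  h_y - h_cond
}
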
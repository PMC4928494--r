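# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture_image_size <- c(300, 400) # 12 x 16 dva at 25 px/dva

fixture_targets <- function() {
  cbind(x = c(80, 300, 150, 320, 60), y = c(60, 100, 250, 220, 150))
}

# Small labeled corpus + extracted profile (the walker's input everywhere).
fixture_profile <- function() {
  if (is.null(.fixtures$profile)) {
    corp <- lapply(1:5, function(i) {
      make_scanpath(oculomotor_spec(), fixture_targets(), n_events = 30,
                    image_size = fixture_image_size, seed = i)
    })
    .fixtures$corpus <- corp
    .fixtures$profile <- extract_profile(lapply(corp, `[[`, "path"),
                                         lapply(corp, `[[`, "labeling"))
  }
  .fixtures$profile
}

fixture_corpus <- function() {
  fixture_profile()
  .fixtures$corpus
}

# A decoupled scene and its salience map (expensive; reused across tests).
fixture_scene <- function() {
  if (is.null(.fixtures$scene)) {
    .fixtures$scene <- make_scene(
      scene_spec(image_size = fixture_image_size, n_blobs = 2,
                 decouple_intensity = TRUE), seed = 21)
    .fixtures$salience <- compute_salience(.fixtures$scene$image, px_per_dva = 25)
  }
  .fixtures$scene
}

fixture_salience <- function() {
  fixture_scene()
  .fixtures$salience
}

# Ground-truth event labeling of a sim_result (events are known exactly:
# path sample 1 is the start position, event step j occupies sample
# start_steps + 1 + j).
sim_to_events <- function(sim) {
  dt <- attr(sim$path, "dt_ms")
  ev <- sim$events
  start_index <- as.integer(round(ev$start_ms / dt)) + 2L
  events <- tibble::tibble(
    kind = ev$kind,
    start_index = start_index,
    end_index = start_index + ev$n_steps - 1L,
    start_ms = ev$start_ms, end_ms = ev$end_ms,
    duration_ms = ev$n_steps * dt,
    x = vapply(seq_len(nrow(ev)), function(i) {
      mean(sim$path$x[start_index[i]:(start_index[i] + ev$n_steps[i] - 1L)])
    }, 0),
    y = vapply(seq_len(nrow(ev)), function(i) {
      mean(sim$path$y[start_index[i]:(start_index[i] + ev$n_steps[i] - 1L)])
    }, 0)
  )
  structure(list(samples = tibble::tibble(time_ms = sim$path$time_ms,
                                          x = sim$path$x, y = sim$path$y,
                                          label = NA_character_),
                 events = events,
                 image_size = attr(sim$path, "image_size"),
                 px_per_dva = attr(sim$path, "px_per_dva"),
                 dt_ms = dt, seed = sim$seed),
            class = "gw_events")
}

# A smooth single-peak map used as a hand-made salience field.
radial_bump_map <- function(h = 300, w = 400, cx = 260, cy = 120, sd = 60) {
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  m <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sd^2))
  structure(m, px_per_dva = 25, kind = "salience",
            class = c("salience_map", "matrix", "array"))
}

# Two-sample Kolmogorov-Smirnov distance (statistic only).
ks_distance <- function(a, b) {
  unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}
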
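#' Specify a synthetic scene
#'
#' Describes an image built from a gray (or luminance-ramp) background and a
#' set of colored blobs that carry color/orientation contrast. With
#' `decouple_intensity = TRUE` the blobs are isoluminant with the background
#' (salient but invisible in the intensity map) and a broad bright patch is
#' placed away from them, so the brightest pixels lie outside the salient
#' hotspots; these decoupled scenes let salience- and intensity-based
#' predictions be told apart.
#'
#' @param image_size `c(H, W)` pixels.
#' @param px_per_dva pixels per dva.
#' @param n_blobs number of salient blobs (used when `blobs` is NULL).
#' @param blobs optional tibble with columns x, y (px), radius_px, contrast
#'   (0, 1\], hue (one of "red", "green", "blue", "yellow").
#' @param background "constant" or "ramp" (vertical luminance ramp).
#' @param background_level background gray level, 0-255 (default 120).
#' @param decouple_intensity make bright regions non-salient (default FALSE).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_size = c(600, 800), px_per_dva = 25,
                       n_blobs = 3, blobs = NULL,
                       background = c("constant", "ramp"),
                       background_level = 120, decouple_intensity = FALSE) {
  background <- match.arg(background)
  structure(list(image_size = image_size, px_per_dva = px_per_dva,
                 n_blobs = n_blobs, blobs = blobs, background = background,
                 background_level = background_level,
                 decouple_intensity = decouple_intensity),
            class = "scene_spec")
}

#' Generate a synthetic scene with known salience ground truth
#'
#' Renders the scene described by a [scene_spec()] and returns the RGB image
#' together with the ground-truth hotspot mask (union of the blob disks).
#' Blob positions are drawn uniformly away from the borders when the spec
#' does not fix them. Same seed, same scene.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed.
#' @return a `scene`: list with `image` (H x W x 3 array, 0-255), `mask`
#'   (logical H x W hotspot mask), `blobs` (tibble) and `spec`.
#' @export
make_scene <- function(spec = scene_spec(), seed = 1) {
  set.seed(as.integer(seed))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  g0 <- spec$background_level

  blobs <- spec$blobs
  if (is.null(blobs)) {
    r_px <- round(1.2 * spec$px_per_dva)
    margin <- 3 * r_px
    hues <- c("red", "green", "blue", "yellow")
    blobs <- tibble::tibble(
      x = stats::runif(spec$n_blobs, margin, w - margin),
      y = stats::runif(spec$n_blobs, margin, h - margin),
      radius_px = r_px,
      contrast = 1,
      hue = hues[(seq_len(spec$n_blobs) - 1L) %% length(hues) + 1L]
    )
  }
  stopifnot(all(blobs$contrast > 0), all(blobs$contrast <= 1))
  if (any(blobs$x < blobs$radius_px | blobs$x > w - blobs$radius_px |
          blobs$y < blobs$radius_px | blobs$y > h - blobs$radius_px)) {
    stop("blobs must lie inside the image")
  }

  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)

  base <- if (spec$background == "ramp") {
    g0 + 40 * (ys / h - 0.5)
  } else {
    matrix(g0, h, w)
  }
  r <- base; g <- base; b <- base

  mask <- matrix(FALSE, h, w)
  overlap <- FALSE
  for (i in seq_len(nrow(blobs))) {
    d <- sqrt((xs - blobs$x[i])^2 + (ys - blobs$y[i])^2)
    disk <- d <= blobs$radius_px[i]
    if (any(disk & mask)) overlap <- TRUE
    mask <- mask | disk
    # soft-edged window so the blob boundary is not a hard aliasing step
    wgt <- pmax(0, pmin(1, (blobs$radius_px[i] - d) / (0.25 * blobs$radius_px[i])))
    delta <- blobs$contrast[i] * min(g0, 255 - g0) / 2
    opp <- switch(blobs$hue[i],
      red = c(2, -1, -1), green = c(-1, 2, -1),
      blue = c(-1, -1, 2), yellow = c(1, 1, -2))
    # zero-mean opponent perturbation: luminance (mean RGB) is unchanged
    r <- r + delta * opp[1] * wgt
    g <- g + delta * opp[2] * wgt
    b <- b + delta * opp[3] * wgt
    if (!spec$decouple_intensity) {
      bump <- 0.4 * delta * wgt
      r <- r + bump; g <- g + bump; b <- b + bump
    }
  }
  if (overlap) warning("overlapping blobs; hotspot mask is their union")

  if (spec$decouple_intensity) {
    # broad, low-contrast bright patch centered far from every blob
    cand <- expand.grid(x = seq(0.2, 0.8, by = 0.1) * w,
                        y = seq(0.2, 0.8, by = 0.1) * h)
    dmin <- vapply(seq_len(nrow(cand)), function(i) {
      min(sqrt((cand$x[i] - blobs$x)^2 + (cand$y[i] - blobs$y)^2))
    }, 0)
    ctr <- cand[which.max(dmin), ]
    sig <- 0.35 * min(h, w)
    bump <- (250 - g0) * exp(-((xs - ctr$x)^2 + (ys - ctr$y)^2) / (2 * sig^2))
    r <- r + bump; g <- g + bump; b <- b + bump
  }

  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- pmin(pmax(r, 0), 255)
  img[, , 2] <- pmin(pmax(g, 0), 255)
  img[, , 3] <- pmin(pmax(b, 0), 255)
  structure(list(image = img, mask = mask, blobs = blobs, spec = spec),
            class = "scene")
}

#' Specify synthetic oculomotor statistics
#'
#' Parameter families for the scan-path generator. Durations are lognormal
#' (positive and right-skewed, as empirical duration histograms are) with
#' the configured means, truncated at the 25/10 ms minimums; saccades follow
#' a symmetric raised-cosine velocity profile; fixations jitter isotropically
#' around their target. By construction saccades are straighter than
#' fixation jitter, so the generated corpus carries the
#' persistence(saccade) > persistence(fixation) ordering.
#'
#' @param fix_dur_mean_ms,fix_dur_sd_ms fixation-duration mean/sd (default
#'   215 / 90 ms).
#' @param sac_dur_mean_ms,sac_dur_sd_ms saccade-duration mean/sd (default
#'   56 / 12 ms).
#' @param noise_sd_dva fixation jitter sd in dva (default 0.1).
#' @param persistence_saccade per-step probability that the raw saccade
#'   path stays on course (default 0.9); the complement is realized as
#'   occasional direction kinks, held a few samples and followed by
#'   re-aiming at the target, emulating motor/tracker noise. Persistence
#'   estimated on the smoothed trace will read higher than this raw-path
#'   target. Fixation persistence is not a parameter: isotropic jitter pins
#'   it near 0.25, well below the saccade value, giving the
#'   saccade > fixation ordering.
#' @param horizontal_bias weight of a horizontal bias in departure angles
#'   (0 = isotropic; default 0).
#' @param sample_rate_hz sampling rate (default 200).
#' @param min_fix_ms,min_sac_ms duration floors (25 / 10 ms).
#' @return an `oculomotor_spec` list.
#' @export
oculomotor_spec <- function(fix_dur_mean_ms = 215, fix_dur_sd_ms = 90,
                            sac_dur_mean_ms = 56, sac_dur_sd_ms = 12,
                            noise_sd_dva = 0.1, persistence_saccade = 0.9,
                            horizontal_bias = 0,
                            sample_rate_hz = 200,
                            min_fix_ms = 25, min_sac_ms = 10) {
  stopifnot(fix_dur_mean_ms > min_fix_ms, sac_dur_mean_ms > min_sac_ms,
            persistence_saccade > 0, persistence_saccade <= 1)
  structure(list(fix_dur_mean_ms = fix_dur_mean_ms, fix_dur_sd_ms = fix_dur_sd_ms,
                 sac_dur_mean_ms = sac_dur_mean_ms, sac_dur_sd_ms = sac_dur_sd_ms,
                 noise_sd_dva = noise_sd_dva,
                 persistence_saccade = persistence_saccade,
                 horizontal_bias = horizontal_bias,
                 sample_rate_hz = sample_rate_hz,
                 min_fix_ms = min_fix_ms, min_sac_ms = min_sac_ms),
            class = "oculomotor_spec")
}

# lognormal draws with a given mean/sd, re-drawn until above the floor
rlnorm_mean_sd <- function(n, mean, sd, floor) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  out <- stats::rlnorm(n, meanlog, sdlog)
  bad <- out < floor
  while (any(bad)) {
    out[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
    bad <- out < floor
  }
  out
}

#' Generate a synthetic scan path with exact ground-truth events
#'
#' Alternates fixations (Gaussian jitter around each target) and saccades
#' (straight path with a raised-cosine velocity profile between targets),
#' sampled at 200 Hz, and returns the exact per-sample labels and event
#' table the generator used, so detectors and extractors can be scored
#' against ground truth.
#'
#' @param spec an [oculomotor_spec()].
#' @param targets matrix or data frame of fixation target positions (px);
#'   recycled if fewer than `n_events` rows.
#' @param n_events number of fixations (the path has `n_events - 1`
#'   saccades).
#' @param image_size `c(H, W)` pixels.
#' @param seed integer seed.
#' @param px_per_dva pixels per dva.
#' @return list with `path` (a [scan_path()]) and `labeling` (a `gw_events`
#'   with ground-truth `samples` and `events`).
#' @export
make_scanpath <- function(spec = oculomotor_spec(), targets, n_events,
                          image_size, seed = 1, px_per_dva = 25) {
  stopifnot(n_events >= 2)
  set.seed(as.integer(seed))
  tg <- as_fix_matrix(targets)
  if (any(tg[, 1] < 0 | tg[, 1] > image_size[2] |
          tg[, 2] < 0 | tg[, 2] > image_size[1])) {
    stop("targets outside image")
  }
  tg <- tg[rep_len(seq_len(nrow(tg)), n_events), , drop = FALSE]

  dt <- 1000 / spec$sample_rate_hz
  noise_px <- spec$noise_sd_dva * px_per_dva

  fix_dur <- rlnorm_mean_sd(n_events, spec$fix_dur_mean_ms, spec$fix_dur_sd_ms,
                            spec$min_fix_ms)
  sac_dur <- rlnorm_mean_sd(n_events - 1, spec$sac_dur_mean_ms, spec$sac_dur_sd_ms,
                            spec$min_sac_ms)

  xs <- numeric(0); ys <- numeric(0); lab <- character(0)
  ev <- list()
  pos <- tg[1, ]
  for (i in seq_len(n_events)) {
    nf <- max(ceiling(spec$min_fix_ms / dt), round(fix_dur[i] / dt))
    fx <- tg[i, 1] + stats::rnorm(nf, 0, noise_px)
    fy <- tg[i, 2] + stats::rnorm(nf, 0, noise_px)
    fx <- pmin(pmax(fx, 0), image_size[2]); fy <- pmin(pmax(fy, 0), image_size[1])
    ev[[length(ev) + 1]] <- c(kind = "fixation", start = length(xs) + 1L, len = nf)
    xs <- c(xs, fx); ys <- c(ys, fy); lab <- c(lab, rep("fixation", nf))
    if (i < n_events) {
      ns <- max(ceiling(spec$min_sac_ms / dt), round(sac_dur[i] / dt))
      # raised-cosine speed bump toward the target; with probability
      # (1 - persistence_saccade) a step kinks off-course and later steps
      # re-aim, so the landing point is exact but the path is not straight
      prof <- 1 - cos(2 * pi * (seq_len(ns) - 0.5) / ns)
      cur <- tg[i, ]; to <- tg[i + 1, ]
      sx <- numeric(ns); sy <- numeric(ns)
      # a kink holds its deviated heading for a few samples so it survives
      # the 30 ms position smoothing used when persistence is estimated
      kink_hold <- 3L
      kink_rate <- (1 - spec$persistence_saccade) / kink_hold
      kink_left <- 0L; kink_off <- 0
      for (j in seq_len(ns)) {
        rem <- to - cur
        d <- sqrt(sum(rem^2))
        dir <- if (d > 0) atan2(rem[2], rem[1]) else 0
        if (kink_left > 0L) {
          dir <- dir + kink_off
          kink_left <- kink_left - 1L
        } else if (j < ns - kink_hold && stats::runif(1) < kink_rate) {
          kink_off <- sample(c(-1, 1), 1) * stats::runif(1, deg2rad(60), deg2rad(120))
          kink_left <- kink_hold
          dir <- dir + kink_off
        }
        v <- if (j == ns) d else d * prof[j] / sum(prof[j:ns])
        cur <- cur + v * c(cos(dir), sin(dir))
        sx[j] <- cur[1]; sy[j] <- cur[2]
      }
      sx <- pmin(pmax(sx, 0), image_size[2]); sy <- pmin(pmax(sy, 0), image_size[1])
      ev[[length(ev) + 1]] <- c(kind = "saccade", start = length(xs) + 1L, len = ns)
      xs <- c(xs, sx); ys <- c(ys, sy); lab <- c(lab, rep("saccade", ns))
    }
  }

  n <- length(xs)
  path <- scan_path(seq(0, by = dt, length.out = n), xs, ys,
                    image_size = image_size, px_per_dva = px_per_dva)
  events <- dplyr::bind_rows(lapply(ev, function(e) {
    s <- as.integer(e[["start"]]); l <- as.integer(e[["len"]])
    tibble::tibble(kind = e[["kind"]], start_index = s, end_index = s + l - 1L,
                   start_ms = (s - 1L) * dt, end_ms = (s + l - 2L) * dt,
                   duration_ms = l * dt,
                   x = mean(xs[s:(s + l - 1L)]), y = mean(ys[s:(s + l - 1L)]))
  }))
  samples <- tibble::tibble(time_ms = path$time_ms, x = xs, y = ys, label = lab)
  labeling <- structure(list(samples = samples, events = events,
                             image_size = image_size, px_per_dva = px_per_dva,
                             dt_ms = dt, seed = seed),
                        class = "gw_events")
  list(path = path, labeling = labeling)
}

#' Generate a shift-task dataset
#'
#' For each image: a synthetic scene on the shift-task geometry (378 x 756
#' px, 16 x 32 dva), a horizontal image offset of +/-2 dva relative to the
#' monitor center, and nine initial fixation-cross positions - the image
#' center plus the eight cardinal/intermediate compass points placed 1 dva
#' inside the image border (so crosses sit up to ~15 dva horizontally and
#' ~7 dva vertically from the center).
#'
#' @param spec a [scene_spec()] template; its size/px_per_dva are overridden
#'   by the shift-task geometry unless `geometry = FALSE`.
#' @param n_images number of images.
#' @param seed integer seed.
#' @param image_size,px_per_dva shift-task geometry defaults.
#' @return list with `scenes` (list of `scene`) and `conditions` (tibble:
#'   image_id, offset_dva, cross_id, cross_x_px, cross_y_px, cross_dx_dva,
#'   cross_dy_dva).
#' @export
make_shift_task <- function(spec = scene_spec(), n_images = 1, seed = 1,
                            image_size = c(378, 756), px_per_dva = 756 / 32) {
  stopifnot(n_images >= 1)
  set.seed(as.integer(seed))
  sp <- spec
  sp$image_size <- image_size
  sp$px_per_dva <- px_per_dva
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n_images)
  offsets <- sample(c(-2, 2), n_images, replace = TRUE)
  scenes <- lapply(scene_seeds, function(s) make_scene(sp, seed = s))

  h <- image_size[1]; w <- image_size[2]
  inset <- 1 * px_per_dva
  cx <- w / 2; cy <- h / 2
  xe <- c(inset, w - inset); ye <- c(inset, h - inset)
  cross <- tibble::tibble(
    cross_id = c("center", "n", "ne", "e", "se", "s", "sw", "w", "nw"),
    cross_x_px = c(cx, cx, xe[2], xe[2], xe[2], cx, xe[1], xe[1], xe[1]),
    cross_y_px = c(cy, ye[1], ye[1], cy, ye[2], ye[2], ye[2], cy, ye[1])
  )
  conditions <- purrr::map_dfr(seq_len(n_images), function(i) {
    dplyr::mutate(cross, image_id = i, offset_dva = offsets[i],
                  cross_dx_dva = (cross_x_px - cx) / px_per_dva,
                  cross_dy_dva = (cross_y_px - cy) / px_per_dva)
  })
  list(scenes = scenes, conditions = conditions)
}
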
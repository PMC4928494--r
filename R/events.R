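#' Construct a scan path
#'
#' A scan path is a uniformly sampled gaze recording: a tibble with columns
#' `time_ms`, `x`, `y` (pixels, origin at the image's top-left corner, x
#' rightward, y downward, continuous coordinates on \[0, W\] x \[0, H\]) and
#' attributes `image_size = c(H, W)`, `px_per_dva` and the sampling interval
#' `dt_ms` (5 ms at the default 200 Hz).
#'
#' @param time_ms sample times in ms, strictly increasing with constant step.
#' @param x,y gaze position in pixels.
#' @param image_size `c(H, W)` of the viewed image, pixels.
#' @param px_per_dva pixels per degree of visual angle.
#' @return a `scan_path` tibble.
#' @export
scan_path <- function(time_ms, x, y, image_size, px_per_dva = 25) {
  stopifnot(length(time_ms) == length(x), length(x) == length(y),
            length(image_size) == 2)
  if (length(time_ms) >= 2) {
    steps <- diff(time_ms)
    if (any(steps <= 0)) stop("time_ms must be strictly increasing")
    if (diff(range(steps)) > 1e-6 * mean(steps)) {
      stop("time_ms must be uniformly sampled")
    }
    dt <- steps[1]
  } else {
    dt <- 5
  }
  out <- tibble::tibble(time_ms = as.numeric(time_ms),
                        x = as.numeric(x), y = as.numeric(y))
  structure(out, image_size = as.numeric(image_size),
            px_per_dva = px_per_dva, dt_ms = dt,
            class = c("scan_path", class(out)))
}

path_dt <- function(path) attr(path, "dt_ms") %||% 5
path_size <- function(path) attr(path, "image_size")

#' Preprocess raw gaze samples against the image bounds
#'
#' Samples more than `margin_px` (1 dva by default) outside the image are
#' marked excluded; samples outside the image but within the margin are moved
#' to the closest point on the image (small calibration errors at the edges).
#'
#' @param path a [scan_path()].
#' @param margin_px exclusion margin in pixels (default: one dva).
#' @return the scan path with an `excluded` logical column and clamped
#'   coordinates.
#' @export
preprocess_gaze <- function(path, margin_px = NULL) {
  sz <- path_size(path)
  if (is.null(sz)) stop("scan path has no image_size attribute")
  margin_px <- margin_px %||% (attr(path, "px_per_dva") %||% 25)
  dx <- pmax(pmax(0 - path$x, path$x - sz[2]), 0)
  dy <- pmax(pmax(0 - path$y, path$y - sz[1]), 0)
  excl <- (dx > margin_px) | (dy > margin_px) | !is.finite(path$x) | !is.finite(path$y)
  cl <- clamp_to_image(path$x, path$y, sz)
  out <- path
  out$x <- ifelse(excl, path$x, cl$x)
  out$y <- ifelse(excl, path$y, cl$y)
  out$excluded <- excl
  if (all(excl)) stop("all gaze samples fall outside the image (plus margin)")
  out
}

#' Per-sample kinematic state of a scan path
#'
#' Computes the four state-space parameters used by the event classifier:
#' step distance (px), velocity (px/s), acceleration (px/s^2) and angular
#' velocity (rad/s). Position is smoothed with a centered moving average
#' (default 30 ms) before differencing; velocity/acceleration use central
#' finite differences; angular velocity is the wrapped change in movement
#' direction per sample divided by the sampling interval.
#'
#' @param path a [scan_path()].
#' @param smooth_ms moving-average window in ms (0 disables smoothing).
#' @return a tibble with columns `dist`, `vel`, `acc`, `angvel`.
#' @export
kinematics <- function(path, smooth_ms = 30) {
  n <- nrow(path)
  if (n < 4) stop("kinematics requires at least 4 samples")
  dt <- path_dt(path) / 1000 # seconds
  width <- max(1L, round(smooth_ms / (dt * 1000)))
  if (width %% 2L == 0L) width <- width + 1L
  xs <- moving_average(path$x, width)
  ys <- moving_average(path$y, width)

  ddx <- c(xs[2] - xs[1], diff(xs))
  ddy <- c(ys[2] - ys[1], diff(ys))
  dist <- sqrt(ddx^2 + ddy^2)

  cdiff <- function(v) {
    d <- numeric(length(v))
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
    d[1] <- v[2] - v[1]; d[n] <- v[n] - v[n - 1]
    d
  }
  vx <- cdiff(xs) / dt
  vy <- cdiff(ys) / dt
  vel <- sqrt(vx^2 + vy^2)
  acc <- abs(cdiff(vel)) / dt

  dir <- atan2(ddy, ddx)
  moved <- dist > 1e-9
  # carry the last defined direction through stationary stretches
  if (any(moved)) {
    last <- dir[which(moved)[1]]
    for (i in seq_len(n)) {
      if (moved[i]) last <- dir[i] else dir[i] <- last
    }
  } else {
    dir[] <- 0
  }
  angvel <- c(0, abs(wrap_angle(diff(dir)))) / dt

  tibble::tibble(dist = dist, vel = vel, acc = acc, angvel = angvel)
}

#' Detect fixations and saccades with a k-means state-space classifier
#'
#' Clusters the z-scored kinematic state (distance, velocity, acceleration,
#' angular velocity) with k-means (k swept over `k_range`, chosen by mean
#' silhouette width); clusters whose mean velocity exceeds the global mean
#' velocity are saccade clusters. Adjacent same-label runs are merged and
#' runs shorter than the minimum fixation (25 ms) or saccade (10 ms)
#' duration are absorbed into their flanking events. Excluded samples split
#' the path into segments; events never span an exclusion gap.
#'
#' @param path a [scan_path()]; preprocessed with [preprocess_gaze()] first
#'   if it has an `excluded` column requirement (done automatically).
#' @param seed integer seed for the k-means initialization.
#' @param min_fix_ms,min_sac_ms minimum event durations in ms.
#' @param k_range candidate numbers of clusters.
#' @return a `gw_events` object: a list with `samples` (tibble: time_ms, x,
#'   y, label in fixation/saccade/excluded) and `events` (tibble: kind,
#'   start_index, end_index, start_ms, end_ms, duration_ms, x, y with x/y
#'   the mean gaze position of the event).
#' @export
detect_events <- function(path, seed = 1, min_fix_ms = 25, min_sac_ms = 10,
                          k_range = 2:5) {
  if (!"excluded" %in% names(path)) path <- preprocess_gaze(path)
  n <- nrow(path)
  if (n < 50) stop("need at least 50 samples (250 ms) for segmentation")
  dt <- path_dt(path)

  segs <- contiguous_runs(!path$excluded)
  segs <- segs[segs$value & (segs$end - segs$start + 1) >= 8, , drop = FALSE]
  if (!nrow(segs)) stop("no usable on-image segments")

  feats <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    sub <- path[segs$start[i]:segs$end[i], , drop = FALSE]
    attr(sub, "dt_ms") <- dt; attr(sub, "image_size") <- path_size(path)
    class(sub) <- class(path)
    feats[[i]] <- kinematics(sub)
  }
  kin <- dplyr::bind_rows(feats)

  zs <- scale(as.matrix(kin))
  zs[, apply(as.matrix(kin), 2, stats::sd) < 1e-12] <- 0
  zs[!is.finite(zs)] <- 0

  lab_pool <- if (max(kin$vel) - min(kin$vel) < 1e-9) {
    rep("fixation", nrow(kin)) # degenerate: no movement at all
  } else {
    cl <- kmeans_states(zs, k_range, seed)
    sac_clusters <- which(tapply(kin$vel, cl, mean) > mean(kin$vel))
    ifelse(cl %in% as.integer(names(tapply(kin$vel, cl, mean)))[sac_clusters],
           "saccade", "fixation")
  }

  labels <- rep("excluded", n)
  off <- 0L
  for (i in seq_len(nrow(segs))) {
    len <- segs$end[i] - segs$start[i] + 1L
    seg_lab <- lab_pool[(off + 1L):(off + len)]
    seg_lab <- enforce_min_durations(seg_lab, dt, min_fix_ms, min_sac_ms)
    labels[segs$start[i]:segs$end[i]] <- seg_lab
    off <- off + len
  }

  events <- build_event_table(labels, path, dt, min_fix_ms, min_sac_ms)
  samples <- tibble::tibble(time_ms = path$time_ms, x = path$x, y = path$y,
                            label = labels)
  structure(list(samples = samples, events = events,
                 image_size = path_size(path),
                 px_per_dva = attr(path, "px_per_dva") %||% 25,
                 dt_ms = dt, seed = seed),
            class = "gw_events")
}

#' @export
print.gw_events <- function(x, ...) {
  k <- table(x$events$kind)
  cat(sprintf("<gw_events %d samples: %s fixations, %s saccades>\n",
              nrow(x$samples), k[["fixation"]] %||% 0, k[["saccade"]] %||% 0))
  invisible(x)
}

# ---- internals --------------------------------------------------------------

contiguous_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, start = ends - r$lengths + 1L, end = ends)
}

kmeans_states <- function(zs, k_range, seed) {
  set.seed(as.integer(seed))
  n <- nrow(zs)
  sil_idx <- if (n > 1500) sample.int(n, 1500) else seq_len(n)
  best <- NULL; best_sil <- -Inf
  for (k in k_range) {
    if (k >= n) next
    km <- tryCatch(stats::kmeans(zs, centers = k, nstart = 5, iter.max = 100),
                   error = function(e) NULL)
    if (is.null(km)) next
    if (k == 1 || length(unique(km$cluster[sil_idx])) < 2) {
      sil <- -Inf
    } else {
      sw <- cluster::silhouette(km$cluster[sil_idx], stats::dist(zs[sil_idx, , drop = FALSE]))
      sil <- mean(sw[, "sil_width"])
    }
    if (sil > best_sil) {
      best_sil <- sil; best <- km$cluster
    }
  }
  if (is.null(best)) rep(1L, n) else best
}

# Absorb runs shorter than their kind's minimum duration into the flanking
# label, repeatedly, until every run is admissible.
enforce_min_durations <- function(lab, dt, min_fix_ms, min_sac_ms) {
  min_len <- function(kind) {
    ceiling((if (kind == "fixation") min_fix_ms else min_sac_ms) / dt)
  }
  repeat {
    r <- contiguous_runs(lab)
    short <- which(vapply(seq_len(nrow(r)), function(i) {
      r$end[i] - r$start[i] + 1L < min_len(r$value[i])
    }, logical(1)))
    if (!length(short)) break
    # absorb the shortest offending run first
    lens <- r$end[short] - r$start[short] + 1L
    i <- short[which.min(lens)]
    other <- if (r$value[i] == "fixation") "saccade" else "fixation"
    lab[r$start[i]:r$end[i]] <- if (nrow(r) == 1) r$value[i] else other
    if (nrow(r) == 1) break
  }
  lab
}

build_event_table <- function(labels, path, dt, min_fix_ms, min_sac_ms) {
  r <- contiguous_runs(labels)
  r <- r[r$value != "excluded", , drop = FALSE]
  if (!nrow(r)) stop("no events detected")
  kind <- r$value
  out <- tibble::tibble(
    kind = kind,
    start_index = r$start, end_index = r$end,
    start_ms = path$time_ms[r$start], end_ms = path$time_ms[r$end],
    duration_ms = (r$end - r$start + 1L) * dt,
    x = vapply(seq_len(nrow(r)), function(i) mean(path$x[r$start[i]:r$end[i]]), 0),
    y = vapply(seq_len(nrow(r)), function(i) mean(path$y[r$start[i]:r$end[i]]), 0)
  )
  out
}
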
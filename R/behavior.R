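#' Time-warp a series to a target length
#'
#' Rescales a per-sample series to `target_length` points by sampling at
#' linearly spaced positions with linear interpolation, so events of varying
#' duration can be aggregated on a common (median-length) time axis. The
#' endpoints are preserved exactly.
#'
#' @param series numeric vector, length at least 2.
#' @param target_length output length, at least 2.
#' @return numeric vector of length `target_length`.
#' @export
#' @examples
#' time_warp(c(0, 10), 3) # 0 5 10
time_warp <- function(series, target_length) {
  n <- length(series)
  if (n == 0) stop("cannot warp an empty series")
  if (n == 1) return(rep(series, target_length))
  stopifnot(target_length >= 2)
  stats::approx(seq_len(n), series, xout = seq(1, n, length.out = target_length))$y
}

#' Extract the oculomotor statistics that parameterize the walker
#'
#' Pools event statistics across one or more labeled scan paths: fixation
#' and saccade durations; the circular distribution of saccade departure
#' angles (measured from the preceding fixation's centroid to the gaze
#' position a short lag into the saccade, binned at `angle_bin_deg`);
#' per-warped-time-step empirical velocity distributions (quantile knots of
#' speed in px per sample step, events warped to the median event length);
#' and per-warped-time-step persistence, the probability that the movement
#' direction changed by no more than 45 degrees between successive samples.
#'
#' @param paths a [scan_path()] or list of them.
#' @param labelings a `gw_events` object (from [detect_events()] or the
#'   synthetic generator) or list matching `paths`.
#' @param angle_bin_deg departure-angle bin width, degrees (default 5).
#' @param departure_lag_samples samples into the saccade at which the
#'   departure direction is measured (default 3, i.e. 15 ms at 200 Hz).
#' @param n_quantile_knots quantile knots per warped step of the velocity
#'   distributions (default 100).
#' @param smooth_ms position smoothing used for direction changes (default
#'   30, matching [kinematics()]).
#' @return a `behavior_profile` object; see Details.
#' @details The profile fields are `fixation_durations` / `saccade_durations`
#'   (pooled ms samples), `departure_angles` (probability per bin, sums to
#'   1, bins on (-180, 180\]), `saccade_velocity_q` / `fixation_velocity_q`
#'   (median-length x knots quantile matrices of speed, px/step),
#'   `persistence_saccade` / `persistence_fixation` (per-warped-step
#'   probabilities) and `medians` (median fixation and saccade duration,
#'   ms).
#' @export
extract_profile <- function(paths, labelings, angle_bin_deg = 5,
                            departure_lag_samples = 3,
                            n_quantile_knots = 100, smooth_ms = 30) {
  if (inherits(paths, "scan_path")) paths <- list(paths)
  if (inherits(labelings, "gw_events")) labelings <- list(labelings)
  stopifnot(length(paths) == length(labelings), length(paths) >= 1)
  dt <- path_dt(paths[[1]])

  fix_dur <- numeric(); sac_dur <- numeric()
  sac_vel <- list(); fix_vel <- list()
  sac_per <- list(); fix_per <- list()
  dep_ang <- numeric()

  for (p in seq_along(paths)) {
    path <- paths[[p]]; ev <- labelings[[p]]$events
    width <- max(1L, round(smooth_ms / dt)); if (width %% 2L == 0L) width <- width + 1L
    xs <- moving_average(path$x, width); ys <- moving_average(path$y, width)
    stepx <- diff(xs); stepy <- diff(ys)
    dirs <- atan2(stepy, stepx)
    dirs[sqrt(stepx^2 + stepy^2) < 1e-9] <- NA
    turn_ok <- abs(wrap_angle(diff(dirs))) <= deg2rad(45)
    # no measurable movement: the direction trivially did not change
    turn_ok[is.na(turn_ok)] <- TRUE
    turn_ok <- as.numeric(turn_ok)

    spd_raw <- sqrt(diff(path$x)^2 + diff(path$y)^2) # px per step, unsmoothed

    for (i in seq_len(nrow(ev))) {
      a <- ev$start_index[i]; b <- ev$end_index[i]
      kind <- ev$kind[i]
      dur <- ev$duration_ms[i]
      # per-step speed within the event (between consecutive event samples)
      v <- if (b > a) spd_raw[a:(b - 1)] else numeric(0)
      # direction-change indicators at interior samples
      ok <- if (b - a >= 2) turn_ok[a:(b - 2)] else logical(0)
      if (kind == "fixation") {
        fix_dur <- c(fix_dur, dur)
        if (length(v) >= 2) fix_vel[[length(fix_vel) + 1]] <- v
        if (length(ok) >= 2) fix_per[[length(fix_per) + 1]] <- ok
      } else {
        sac_dur <- c(sac_dur, dur)
        if (length(v) >= 2) sac_vel[[length(sac_vel) + 1]] <- v
        if (length(ok) >= 2) sac_per[[length(sac_per) + 1]] <- ok
        if (i > 1 && ev$kind[i - 1] == "fixation") {
          j <- min(a + departure_lag_samples, b)
          dx <- path$x[j] - ev$x[i - 1]; dy <- path$y[j] - ev$y[i - 1]
          if (dx^2 + dy^2 > 0) dep_ang <- c(dep_ang, atan2(dy, dx))
        }
      }
    }
  }

  if (!length(fix_dur)) stop("no fixation events in the corpus; cannot build fixation statistics")
  if (!length(sac_dur)) stop("no saccade events in the corpus; cannot build saccade statistics")
  if (!length(dep_ang)) stop("no fixation-to-saccade transitions; cannot build departure-angle distribution")

  med_fix_steps <- max(2L, round(stats::median(fix_dur) / dt))
  med_sac_steps <- max(2L, round(stats::median(sac_dur) / dt))

  probs <- seq(0, 1, length.out = n_quantile_knots)
  warp_stack <- function(lst, L) {
    if (!length(lst)) return(NULL)
    do.call(rbind, lapply(lst, time_warp, target_length = L))
  }
  vel_q <- function(lst, L) {
    m <- warp_stack(lst, L)
    if (is.null(m)) stop("too few events with usable velocity series")
    t(apply(m, 2, stats::quantile, probs = probs, names = FALSE))
  }
  persistence <- function(lst, L) {
    m <- warp_stack(lst, L)
    if (is.null(m)) rep(0.5, L) else colMeans(m)
  }

  breaks <- seq(-180, 180, by = angle_bin_deg)
  ang_deg <- rad2deg(wrap_angle(dep_ang))
  ang_deg[ang_deg <= -180] <- 180
  cnt <- graphics::hist(ang_deg, breaks = breaks, plot = FALSE)$counts
  dep_pdf <- cnt / sum(cnt)

  structure(list(
    fixation_durations = fix_dur,
    saccade_durations = sac_dur,
    departure_angles = dep_pdf,
    angle_breaks_deg = breaks,
    saccade_velocity_q = vel_q(sac_vel, med_sac_steps),
    fixation_velocity_q = vel_q(fix_vel, med_fix_steps),
    velocity_probs = probs,
    persistence_saccade = pmin(pmax(persistence(sac_per, med_sac_steps), 0), 1),
    persistence_fixation = pmin(pmax(persistence(fix_per, med_fix_steps), 0), 1),
    medians = c(fixation_ms = stats::median(fix_dur),
                saccade_ms = stats::median(sac_dur)),
    dt_ms = dt,
    n_events = c(fixation = length(fix_dur), saccade = length(sac_dur))
  ), class = "behavior_profile")
}

#' @export
print.behavior_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "<behavior_profile: %d fixations (median %g ms), %d saccades (median %g ms)>\n"),
    x$n_events[["fixation"]], x$medians[["fixation_ms"]],
    x$n_events[["saccade"]], x$medians[["saccade_ms"]]))
  invisible(x)
}

#' Draw from a stored behavioral statistic
#'
#' Empirical sampling from a [behavior_profile][extract_profile()]:
#' durations and departure angles are drawn from the stored samples/bins;
#' velocities by inverse-CDF at a given warped time step. Uses the current
#' RNG state; seed the caller for reproducibility.
#'
#' @param profile a `behavior_profile`.
#' @param which one of "fixation_duration", "saccade_duration",
#'   "departure_angle", "fixation_velocity", "saccade_velocity".
#' @param context warped time step (row of the velocity quantile matrix;
#'   may be fractional) for the velocity statistics.
#' @param n number of draws.
#' @return numeric vector: ms for durations, radians for angles, px/step
#'   for velocities.
#' @export
sample_profile <- function(profile, which, context = NULL, n = 1) {
  draw_from <- function(x) x[sample.int(length(x), n, replace = TRUE)]
  switch(which,
    fixation_duration = draw_from(profile$fixation_durations),
    saccade_duration = draw_from(profile$saccade_durations),
    departure_angle = {
      k <- sample.int(length(profile$departure_angles), n, replace = TRUE,
                      prob = profile$departure_angles)
      lo <- profile$angle_breaks_deg[k]
      deg2rad(lo + stats::runif(n) * diff(profile$angle_breaks_deg)[1])
    },
    fixation_velocity = draw_velocity(profile$fixation_velocity_q,
                                      profile$velocity_probs, context, n),
    saccade_velocity = draw_velocity(profile$saccade_velocity_q,
                                     profile$velocity_probs, context, n),
    stop("unknown statistic: ", which)
  )
}

draw_velocity <- function(qmat, probs, context, n) {
  if (is.null(context)) stop("velocity draws need a warped time step (context)")
  row <- interp_row(qmat, context)
  u <- stats::runif(n)
  stats::approx(probs, row, xout = u, rule = 2)$y
}

# Linear interpolation between adjacent rows of a per-step table.
interp_row <- function(m, pos) {
  pos <- min(max(pos, 1), nrow(m))
  lo <- floor(pos); hi <- ceiling(pos)
  if (lo == hi) return(m[lo, ])
  w <- pos - lo
  (1 - w) * m[lo, ] + w * m[hi, ]
}

# Warp the velocity quantile table and persistence vector to an event of
# n_steps samples (linear-spaced row sampling, as in the time warp).
warp_to_duration <- function(profile, kind, n_steps) {
  qmat <- if (kind == "saccade") profile$saccade_velocity_q else profile$fixation_velocity_q
  per <- if (kind == "saccade") profile$persistence_saccade else profile$persistence_fixation
  pos <- seq(1, nrow(qmat), length.out = n_steps)
  list(
    vel_q = do.call(rbind, lapply(pos, function(p) interp_row(qmat, p))),
    persistence = time_warp(per, max(2L, n_steps))[seq_len(n_steps)]
  )
}

#' Serialize / read a behavior profile as JSON
#'
#' @param profile a `behavior_profile`.
#' @param path file path.
#' @return `read_profile` returns a `behavior_profile`; `write_profile`
#'   returns `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  x <- unclass(profile)
  x$schema_version <- 1L
  jsonlite::write_json(x, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$schema_version <- NULL
  for (f in c("saccade_velocity_q", "fixation_velocity_q")) {
    x[[f]] <- as.matrix(x[[f]])
  }
  x$medians <- stats::setNames(as.numeric(x$medians), c("fixation_ms", "saccade_ms"))
  x$n_events <- stats::setNames(as.integer(x$n_events), c("fixation", "saccade"))
  structure(x, class = "behavior_profile")
}
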
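#' Simulation configuration for the random-walk models
#'
#' Bundles the walker's fixed parameters. The four free parameters (border
#' buffer, border saccade distance, IOR time constant and IOR radius)
#' default to their best-fit values; [sweep_grid()] exposes the full grids
#' they were swept over.
#'
#' @param dt_ms simulation time step, ms (5 ms = 200 Hz).
#' @param total_time_ms simulated viewing time, ms (default 10 s).
#' @param smoothing_sigma_dva Gaussian smoothing of the salience map before
#'   simulation, dva (default 0.5).
#' @param border_buffer_dva distance from the image border inside which the
#'   walk is pushed away from the border (default 1).
#' @param border_saccade_distance_dva inward displacement applied when the
#'   walk leaves the image (default 2).
#' @param ior_radius_dva radius of the inhibition-of-return disk (default 2).
#' @param ior_tau IOR time constant per fixation; salience recovers after
#'   `1/ior_tau` subsequent fixations (default 1/17; 0 disables recovery,
#'   1 recovers at the next fixation).
#' @param fixation_loc_window_ms window at the end of a fixation over which
#'   its location is averaged (default 25 ms = 5 steps).
#' @param n_runs ensemble size for [run_ensemble()] (default 100).
#' @param px_per_dva pixels per degree of visual angle.
#' @param start `c(x, y)` start position in px, or NULL for the image center.
#' @param recompute_gradient recompute the salience gradient locally after
#'   each IOR update (TRUE, default) or keep the initial gradient field.
#' @return a `sim_config` list.
#' @export
sim_config <- function(dt_ms = 5, total_time_ms = 10000,
                       smoothing_sigma_dva = 0.5,
                       border_buffer_dva = 1, border_saccade_distance_dva = 2,
                       ior_radius_dva = 2, ior_tau = 1 / 17,
                       fixation_loc_window_ms = 25,
                       n_runs = 100, px_per_dva = 25, start = NULL,
                       recompute_gradient = TRUE) {
  stopifnot(dt_ms > 0, total_time_ms > 0, ior_tau >= 0, ior_tau <= 1,
            ior_radius_dva >= 0, border_buffer_dva >= 0,
            border_saccade_distance_dva > 0, n_runs >= 1, px_per_dva > 0)
  structure(list(
    dt_ms = dt_ms, total_time_ms = total_time_ms,
    smoothing_sigma_dva = smoothing_sigma_dva,
    border_buffer_dva = border_buffer_dva,
    border_saccade_distance_dva = border_saccade_distance_dva,
    ior_radius_dva = ior_radius_dva, ior_tau = ior_tau,
    fixation_loc_window_ms = fixation_loc_window_ms,
    n_runs = n_runs, px_per_dva = px_per_dva, start = start,
    recompute_gradient = recompute_gradient
  ), class = "sim_config")
}

#' Parameter-sweep grids for the walker's free parameters
#'
#' @return a tibble with columns `parameter` and `value`, one row per swept
#'   cell (each parameter varied with the others held at their defaults).
#' @export
sweep_grid <- function() {
  dplyr::bind_rows(
    tibble::tibble(parameter = "border_buffer_dva",
                   value = c(0.04, 0.4, 1, 2, 4)),
    tibble::tibble(parameter = "border_saccade_distance_dva",
                   value = c(0.4, 1, 2, 4, 8)),
    tibble::tibble(parameter = "ior_tau",
                   value = c(0, 1/50, 1/35, 1/25, 1/17, 1/12, 1/7, 1/3, 1)),
    tibble::tibble(parameter = "ior_radius_dva", value = c(0, 1, 2, 4))
  )
}

#' Prepare the mutable salience state for simulation
#'
#' Smooths the salience map with a Gaussian (sd = 0.5 dva by default) so the
#' walk can climb salience peaks, computes the finite-difference gradient
#' field whose direction is the salience bias, and initializes the
#' inhibition-of-return (IOR) ledger. The state is a mutable environment:
#' `current` equals the smoothed `base` map except where an active IOR entry
#' has consumed (zeroed) salience, and the ledger always holds exactly the
#' consumed values, so `base` can be reconstructed at every step.
#'
#' @param map a `salience_map` (or plain H x W matrix).
#' @param config a [sim_config()] with matching `px_per_dva`.
#' @return a `salience_state` environment with fields `base`, `current`,
#'   `gx`, `gy`, `ledger`, `n_fix`.
#' @export
prepare_salience_state <- function(map, config = sim_config()) {
  stopifnot(is.matrix(map))
  mp <- attr(map, "px_per_dva")
  if (!is.null(mp) && abs(mp - config$px_per_dva) > 1e-9) {
    stop("map px_per_dva (", mp, ") does not match config (", config$px_per_dva, ")")
  }
  base <- blur_gaussian(unclass(map), config$smoothing_sigma_dva * config$px_per_dva)
  st <- new.env(parent = emptyenv())
  st$base <- base
  st$current <- base
  g <- finite_gradient(base)
  st$gx <- g$gx; st$gy <- g$gy
  st$ledger <- list()
  st$n_fix <- 0L
  st$config <- config
  st$disk <- disk_offsets(config$ior_radius_dva * config$px_per_dva)
  class(st) <- "salience_state"
  st
}

#' Combine previous movement direction with the bias direction
#'
#' The persistence-weighted combination
#' `persistence * previous + (1 - persistence) * bias`, implemented as the
#' weighted sum of unit vectors renormalized to a direction (averaging raw
#' angles is discontinuous at +/-180 degrees). A zero resultant keeps the
#' previous direction.
#'
#' @param prev_dir,bias_dir directions in radians.
#' @param persistence weight on the previous direction, in \[0, 1\].
#' @return direction in radians on (-pi, pi\].
#' @export
step_direction <- function(prev_dir, bias_dir, persistence) {
  stopifnot(persistence >= 0, persistence <= 1)
  vx <- persistence * cos(prev_dir) + (1 - persistence) * cos(bias_dir)
  vy <- persistence * sin(prev_dir) + (1 - persistence) * sin(bias_dir)
  if (vx^2 + vy^2 < 1e-24) return(wrap_angle(prev_dir))
  wrap_angle(atan2(vy, vx))
}

# ---- IOR ledger -------------------------------------------------------------

# Zero salience within the IOR disk around a fixation, record the consumed
# values, transfer ownership of already-consumed overlapping pixels to this
# (newer) fixation, and restore any entry that is 1/tau fixations old.
ior_apply <- function(state, fix_x, fix_y) {
  cfg <- state$config
  state$n_fix <- state$n_fix + 1L
  h <- nrow(state$current); w <- ncol(state$current)
  if (nrow(state$disk)) {
    ctr <- px_index(fix_x, fix_y, c(h, w))
    rr <- ctr$row + state$disk[, 1]; cc <- ctr$col + state$disk[, 2]
    keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    idx <- (cc[keep] - 1L) * h + rr[keep]

    vals <- state$current[idx]
    nz <- vals > 0
    entry_idx <- idx[nz]; entry_vals <- vals[nz]
    # take over pixels an older fixation already consumed
    if (length(state$ledger)) {
      covered <- idx[!nz]
      for (k in seq_along(state$ledger)) {
        old <- state$ledger[[k]]
        take <- old$idx %in% covered
        if (any(take)) {
          entry_idx <- c(entry_idx, old$idx[take])
          entry_vals <- c(entry_vals, old$vals[take])
          state$ledger[[k]]$idx <- old$idx[!take]
          state$ledger[[k]]$vals <- old$vals[!take]
        }
      }
    }
    state$current[idx] <- 0
    state$ledger[[length(state$ledger) + 1]] <-
      list(fix_num = state$n_fix, idx = entry_idx, vals = entry_vals)
    update_gradient(state, range(rr[keep]), range(cc[keep]))
  }
  # recovery
  if (cfg$ior_tau > 0 && length(state$ledger)) {
    age_limit <- round(1 / cfg$ior_tau)
    expired <- vapply(state$ledger, function(e) state$n_fix - e$fix_num >= age_limit,
                      logical(1))
    for (e in state$ledger[expired]) {
      if (length(e$idx)) {
        state$current[e$idx] <- e$vals
        rows <- ((e$idx - 1L) %% h) + 1L
        cols <- ((e$idx - 1L) %/% h) + 1L
        update_gradient(state, range(rows), range(cols))
      }
    }
    state$ledger <- state$ledger[!expired]
  }
  invisible(state)
}

# current + ledger-held consumed values must reconstruct base exactly.
ior_reconstruct <- function(state) {
  m <- state$current
  for (e in state$ledger) if (length(e$idx)) m[e$idx] <- e$vals
  m
}

disk_offsets <- function(radius_px) {
  r <- floor(radius_px)
  if (radius_px <= 0) return(matrix(integer(0), 0, 2))
  dr <- rep(-r:r, times = 2 * r + 1)
  dc <- rep(-r:r, each = 2 * r + 1)
  keep <- dr^2 + dc^2 <= radius_px^2
  cbind(dr[keep], dc[keep])
}

finite_gradient <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  if (w >= 3) gx[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  if (w >= 2) { gx[, 1] <- m[, 2] - m[, 1]; gx[, w] <- m[, w] - m[, w - 1] }
  if (h >= 3) gy[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  if (h >= 2) { gy[1, ] <- m[2, ] - m[1, ]; gy[h, ] <- m[h, ] - m[h - 1, ] }
  list(gx = gx, gy = gy)
}

update_gradient <- function(state, row_rng, col_rng) {
  if (!state$config$recompute_gradient) return(invisible(state))
  h <- nrow(state$current); w <- ncol(state$current)
  r0 <- max(1L, row_rng[1] - 1L); r1 <- min(h, row_rng[2] + 1L)
  c0 <- max(1L, col_rng[1] - 1L); c1 <- min(w, col_rng[2] + 1L)
  sub <- state$current[r0:r1, c0:c1, drop = FALSE]
  g <- finite_gradient(sub)
  # interior of the patch has correct central differences; overwrite it
  state$gx[r0:r1, c0:c1] <- g$gx
  state$gy[r0:r1, c0:c1] <- g$gy
  # fix patch-edge columns/rows that have interior neighbors in the full map
  fix_cols <- c(c0, c1); fix_cols <- fix_cols[fix_cols > 1 & fix_cols < w]
  for (cc in fix_cols) {
    state$gx[r0:r1, cc] <- (state$current[r0:r1, cc + 1] - state$current[r0:r1, cc - 1]) / 2
  }
  fix_rows <- c(r0, r1); fix_rows <- fix_rows[fix_rows > 1 & fix_rows < h]
  for (rr in fix_rows) {
    state$gy[rr, c0:c1] <- (state$current[rr + 1, c0:c1] - state$current[rr - 1, c0:c1]) / 2
  }
  invisible(state)
}

bias_direction_at <- function(state, x, y) {
  p <- px_index(x, y, dim(state$current))
  gx <- state$gx[p$row, p$col]; gy <- state$gy[p$row, p$col]
  if (gx == 0 && gy == 0) return(NA_real_)
  atan2(gy, gx)
}

salience_at <- function(state, x, y) {
  p <- px_index(x, y, dim(state$current))
  state$current[p$row, p$col]
}

# ---- movement ---------------------------------------------------------------

# Border rules. Returns the accepted new position.
apply_border_rules <- function(pos, proposed, cfg, h, w) {
  b <- cfg$border_buffer_dva * cfg$px_per_dva
  d2 <- cfg$border_saccade_distance_dva * cfg$px_per_dva
  x <- proposed[1]; y <- proposed[2]
  if (x < 0 || x > w || y < 0 || y > h) {
    # project to the border, then move border_saccade_distance back inside
    bx <- min(max(x, 0), w); by <- min(max(y, 0), h)
    nx <- 0; ny <- 0
    if (x < 0) nx <- 1 else if (x > w) nx <- -1
    if (y < 0) ny <- 1 else if (y > h) ny <- -1
    nrm <- sqrt(nx^2 + ny^2)
    out <- c(bx + d2 * nx / nrm, by + d2 * ny / nrm)
    return(c(min(max(out[1], 0), w), min(max(out[2], 0), h)))
  }
  dx <- x - pos[1]; dy <- y - pos[2]
  # inside the buffer: flip displacement components that point border-ward
  if (x < b && dx < 0) dx <- -dx
  if (x > w - b && dx > 0) dx <- -dx
  if (y < b && dy < 0) dy <- -dy
  if (y > h - b && dy > 0) dy <- -dy
  c(min(max(pos[1] + dx, 0), w), min(max(pos[2] + dy, 0), h))
}

# One saccade or fixation event. `state` is NULL for the CRW. Returns the
# per-step positions and the final direction.
simulate_event <- function(kind, state, profile, cfg, pos, prev_dir, h, w) {
  dur_ms <- sample_profile(profile, paste0(kind, "_duration"))
  n_steps <- max(2L, as.integer(round(dur_ms / cfg$dt_ms)))
  wp <- warp_to_duration(profile, kind, n_steps)
  u <- stats::runif(n_steps)
  vels <- vapply(seq_len(n_steps), function(i) {
    stats::approx(profile$velocity_probs, wp$vel_q[i, ], xout = u[i], rule = 2)$y
  }, 0)

  xs <- numeric(n_steps); ys <- numeric(n_steps)
  crw <- is.null(state)
  for (i in seq_len(n_steps)) {
    if (kind == "saccade" && i == 1L) {
      dir <- sample_profile(profile, "departure_angle")
    } else if (crw) {
      bias <- stats::runif(1, -pi, pi)
      dir <- step_direction(prev_dir, bias, wp$persistence[i])
    } else {
      sal <- salience_at(state, pos[1], pos[2])
      if (kind == "saccade") {
        if (sal == 0) {
          dir <- prev_dir
        } else {
          bias <- bias_direction_at(state, pos[1], pos[2])
          dir <- if (is.na(bias)) prev_dir
                 else step_direction(prev_dir, bias, wp$persistence[i])
        }
      } else {
        bias <- if (sal == 0) sample_profile(profile, "departure_angle")
                else bias_direction_at(state, pos[1], pos[2])
        # undefined gradient (flat salience): fall back to the salience-0 rule
        if (is.na(bias)) bias <- sample_profile(profile, "departure_angle")
        dir <- step_direction(prev_dir, bias, wp$persistence[i])
      }
    }
    proposed <- pos + vels[i] * c(cos(dir), sin(dir))
    newpos <- apply_border_rules(pos, proposed, cfg, h, w)
    disp <- newpos - pos
    if (sum(disp^2) > 1e-18) prev_dir <- atan2(disp[2], disp[1]) else prev_dir <- dir
    pos <- newpos
    xs[i] <- pos[1]; ys[i] <- pos[2]
  }
  list(x = xs, y = ys, dir = prev_dir, n_steps = n_steps)
}

simulate_walk <- function(state, profile, config, image_size, seed, run_id = 1L) {
  set.seed(as.integer(seed))
  h <- image_size[1]; w <- image_size[2]
  cfg <- config
  pos <- cfg$start %||% c(w / 2, h / 2)
  prev_dir <- 0
  n_total <- ceiling(cfg$total_time_ms / cfg$dt_ms)
  xs <- c(pos[1]); ys <- c(pos[2])
  events <- list(); fixations <- list()
  t_steps <- 0L
  loc_window <- max(1L, round(cfg$fixation_loc_window_ms / cfg$dt_ms))

  while (t_steps < n_total) {
    sac <- simulate_event("saccade", state, profile, cfg, pos, prev_dir, h, w)
    events[[length(events) + 1]] <- c(kind = "saccade", start = t_steps,
                                      len = sac$n_steps)
    xs <- c(xs, sac$x); ys <- c(ys, sac$y)
    pos <- c(sac$x[sac$n_steps], sac$y[sac$n_steps]); prev_dir <- sac$dir
    t_steps <- t_steps + sac$n_steps

    fix <- simulate_event("fixation", state, profile, cfg, pos, prev_dir, h, w)
    events[[length(events) + 1]] <- c(kind = "fixation", start = t_steps,
                                      len = fix$n_steps)
    xs <- c(xs, fix$x); ys <- c(ys, fix$y)
    pos <- c(fix$x[fix$n_steps], fix$y[fix$n_steps]); prev_dir <- fix$dir
    k <- min(loc_window, fix$n_steps)
    floc <- c(mean(fix$x[(fix$n_steps - k + 1):fix$n_steps]),
              mean(fix$y[(fix$n_steps - k + 1):fix$n_steps]))
    floc <- c(min(max(floc[1], 0), w), min(max(floc[2], 0), h))
    fixations[[length(fixations) + 1]] <-
      c(x = floc[1], y = floc[2], start_ms = t_steps * cfg$dt_ms,
        duration_ms = fix$n_steps * cfg$dt_ms)
    if (!is.null(state)) ior_apply(state, floc[1], floc[2])
    t_steps <- t_steps + fix$n_steps
  }

  n <- length(xs)
  path <- scan_path(seq(0, by = cfg$dt_ms, length.out = n), xs, ys,
                    image_size = image_size, px_per_dva = cfg$px_per_dva)
  ev <- dplyr::bind_rows(lapply(events, function(e) {
    start <- as.numeric(e[["start"]]); len <- as.numeric(e[["len"]])
    tibble::tibble(kind = e[["kind"]],
                   start_ms = start * cfg$dt_ms,
                   end_ms = (start + len) * cfg$dt_ms,
                   n_steps = len)
  }))
  fx <- tibble::as_tibble(do.call(rbind, fixations))
  fx$fix_index <- seq_len(nrow(fx))
  structure(list(path = path, events = ev, fixations = fx,
                 run_id = run_id, seed = seed,
                 model = if (is.null(state)) "crw" else "bcrw"),
            class = "sim_result")
}

#' Simulate a Biased Correlated Random Walk over a salience map
#'
#' The walk starts at the image center and alternates saccades and fixations
#' until the simulated time reaches `config$total_time_ms` (the final event
#' is completed, so the path can overshoot slightly). Event durations,
#' per-step speeds (warped to the drawn duration) and departure angles are
#' drawn from the behavior profile; movement direction combines the previous
#' direction with the direction of the salience gradient, weighted by the
#' warped persistence. At zero salience a saccade keeps its previous
#' direction and a fixation is biased in a random direction drawn from the
#' departure-angle distribution. Each completed fixation consumes (zeroes)
#' salience within the IOR radius; consumed salience recovers after
#' `1/ior_tau` subsequent fixations.
#'
#' @param map a `salience_map` (any map of matching geometry works).
#' @param profile a `behavior_profile` from [extract_profile()].
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give identical results.
#' @return a `sim_result`: list with `path` (a [scan_path()]), `events`,
#'   `fixations` (tibble x, y, start_ms, duration_ms, fix_index), `run_id`,
#'   `seed`, `model`.
#' @export
simulate_bcrw <- function(map, profile, config = sim_config(), seed = 1) {
  state <- prepare_salience_state(map, config)
  simulate_walk(state, profile, config, dim(map), seed)
}

#' Simulate the salience-free Correlated Random Walk control
#'
#' Identical machinery to [simulate_bcrw()] but the bias direction is an
#' i.i.d. uniformly random direction at every step and there is no
#' inhibition of return.
#'
#' @param profile,config,seed as in [simulate_bcrw()].
#' @param image_size `c(H, W)` in pixels.
#' @return a `sim_result`.
#' @export
simulate_crw <- function(profile, config = sim_config(), image_size, seed = 1) {
  simulate_walk(NULL, profile, config, image_size, seed)
}

#' Run an ensemble of simulations and pool the fixations
#'
#' Runs `config$n_runs` independently seeded walks (sub-seeds derived from
#' `seed`) and pools their fixation locations, the input for
#' [fixation_pdf()].
#'
#' @param map a `salience_map` (ignored for `model = "crw"`).
#' @param profile a `behavior_profile`.
#' @param config a [sim_config()].
#' @param seed master seed.
#' @param model "bcrw" or "crw".
#' @param image_size required for `model = "crw"` when no map is given.
#' @return a list with `results` (list of `sim_result`) and `fixations`
#'   (pooled tibble with a `run_id` column).
#' @export
run_ensemble <- function(map = NULL, profile, config = sim_config(), seed = 1,
                         model = c("bcrw", "crw"), image_size = NULL) {
  model <- match.arg(model)
  if (model == "bcrw" && is.null(map)) stop("the BCRW needs a salience map")
  image_size <- image_size %||% dim(map)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_runs)
  results <- vector("list", config$n_runs)
  for (i in seq_len(config$n_runs)) {
    results[[i]] <- if (model == "bcrw") {
      simulate_bcrw(map, profile, config, seed = seeds[i])
    } else {
      simulate_crw(profile, config, image_size, seed = seeds[i])
    }
    results[[i]]$run_id <- i
  }
  fixations <- dplyr::bind_rows(lapply(results, function(r) {
    dplyr::mutate(r$fixations, run_id = r$run_id)
  }))
  list(results = results, fixations = fixations, model = model, seed = seed)
}

#' Sweep the walker's free parameters against observed fixations
#'
#' Re-runs a small BCRW ensemble for every cell of [sweep_grid()] (one
#' parameter varied at a time, the others at their defaults) and scores each
#' cell by symmetric KL divergence between the predicted and observed
#' fixation PDFs.
#'
#' @param map a `salience_map`.
#' @param profile a `behavior_profile`.
#' @param observed_fixations data frame of observed fixation x/y positions.
#' @param config base [sim_config()].
#' @param n_runs runs per cell (default 10).
#' @param seed master seed.
#' @param grid sweep grid (default [sweep_grid()]).
#' @return a tibble: parameter, value, kl.
#' @export
bcrw_parameter_sweep <- function(map, profile, observed_fixations,
                                 config = sim_config(), n_runs = 10, seed = 1,
                                 grid = sweep_grid()) {
  obs_pdf <- fixation_pdf(observed_fixations, dim(map), config$px_per_dva)
  purrr::pmap_dfr(grid, function(parameter, value) {
    cfg <- config
    cfg[[parameter]] <- value
    cfg$n_runs <- n_runs
    ens <- run_ensemble(map, profile, cfg, seed = seed, model = "bcrw")
    pred <- fixation_pdf(ens$fixations, dim(map), config$px_per_dva)
    tibble::tibble(parameter = parameter, value = value,
                   kl = kl_divergence(pred, obs_pdf))
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result %s: %d samples, %d fixations, seed %s>\n",
              x$model, nrow(x$path), nrow(x$fixations), format(x$seed)))
  invisible(x)
}
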
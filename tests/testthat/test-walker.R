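# BCRW/CRW simulation: direction law, IOR ledger, border rules, ensembles.

test_that("step direction is the persistence-weighted circular combination", {
  expect_equal(step_direction(0.3, 2.1, 1), 0.3)
  expect_equal(step_direction(0.3, 2.1, 0), 2.1)
  # unit-vector mean of 0 and 90 degrees at weight 1/2 is 45 degrees
  expect_equal(step_direction(0, pi / 2, 0.5), pi / 4)
  # antipodal directions at weight 1/2: zero resultant, keep previous
  expect_equal(step_direction(0, pi, 0.5), 0)
})

test_that("the gradient field climbs toward salience peaks", {
  cfg <- sim_config()
  st <- prepare_salience_state(radial_bump_map(), cfg)
  for (pt in list(c(100, 60), c(350, 250), c(50, 280), c(300, 60))) {
    dir <- gazewalk:::bias_direction_at(st, pt[1], pt[2])
    to_peak <- atan2(120 - pt[2], 260 - pt[1])
    expect_lt(abs(gazewalk:::wrap_angle(dir - to_peak)), 0.2)
  }

  flat <- matrix(0.5, 300, 400)
  stf <- prepare_salience_state(flat, cfg)
  expect_true(all(stf$gx == 0))
  expect_true(all(stf$gy == 0))
  expect_true(is.na(gazewalk:::bias_direction_at(stf, 200, 150)))

  bad <- radial_bump_map()
  attr(bad, "px_per_dva") <- 10
  expect_error(prepare_salience_state(bad, cfg), "px_per_dva")
})

test_that("two peaks partition the image into basins of attraction", {
  h <- 300; w <- 400
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  peaks <- list(c(110, 90), c(300, 220))
  m <- exp(-((xs - 110)^2 + (ys - 90)^2) / (2 * 50^2)) +
       exp(-((xs - 300)^2 + (ys - 220)^2) / (2 * 50^2))
  st <- prepare_salience_state(structure(m, px_per_dva = 25), sim_config())
  # numerical ascent oracle: follow the stored gradient from seed points
  for (start in list(c(60, 60), c(160, 140), c(350, 260), c(250, 180))) {
    p <- start
    for (i in 1:4000) {
      d <- gazewalk:::bias_direction_at(st, p[1], p[2])
      if (is.na(d)) break
      p <- p + 1.0 * c(cos(d), sin(d))
      p <- c(min(max(p[1], 1), w - 1), min(max(p[2], 1), h - 1))
    }
    dists <- vapply(peaks, function(pk) sqrt(sum((p - pk)^2)), 0)
    expect_lt(min(dists), 10)
  }
})

test_that("IOR consumes a 2 dva disk and restores it after 1/tau fixations", {
  sal <- fixture_salience()
  cfg <- sim_config()
  st <- prepare_salience_state(sal, cfg)
  base <- st$base
  r_px <- cfg$ior_radius_dva * cfg$px_per_dva

  p1 <- c(120, 100)
  gazewalk:::ior_apply(st, p1[1], p1[2])
  xs <- matrix(rep(seq_len(ncol(base)), each = nrow(base)), nrow(base))
  ys <- matrix(rep(seq_len(nrow(base)), times = ncol(base)), nrow(base))
  disk <- sqrt((xs - 0.5 - (floor(p1[1]) + 0.5))^2 +
               (ys - 0.5 - (floor(p1[2]) + 0.5))^2) <= r_px - 1.5
  expect_true(all(st$current[disk] == 0))
  expect_identical(gazewalk:::ior_reconstruct(st), base)

  # 16 more far-away fixations: still consumed; the 17th restores it
  far <- cbind(x = rep(c(330, 350, 370), length.out = 16),
               y = seq(160, 280, length.out = 16))
  for (i in 1:16) {
    gazewalk:::ior_apply(st, far[i, 1], far[i, 2])
    expect_true(all(st$current[disk] == 0))
    expect_identical(gazewalk:::ior_reconstruct(st), base)
  }
  gazewalk:::ior_apply(st, 250, 270) # far from the first disk
  expect_identical(st$current[disk], base[disk])
  expect_identical(gazewalk:::ior_reconstruct(st), base)
})

test_that("overlapping IOR disks transfer pixel ownership to the newer fixation", {
  sal <- fixture_salience()
  cfg <- sim_config(ior_tau = 1 / 3) # recover after 3 fixations
  st <- prepare_salience_state(sal, cfg)
  base <- st$base
  gazewalk:::ior_apply(st, 150, 150)
  gazewalk:::ior_apply(st, 170, 150) # overlaps the first disk
  expect_identical(gazewalk:::ior_reconstruct(st), base)
  gazewalk:::ior_apply(st, 350, 60)
  gazewalk:::ior_apply(st, 350, 250) # first entry expires here
  # pixels near (170,150) owned by entry 2 must still be consumed
  expect_equal(gazewalk:::salience_at(st, 170, 150), 0)
  expect_identical(gazewalk:::ior_reconstruct(st), base)
})

test_that("border rules keep the walk inside and push 2 dva back in", {
  cfg <- sim_config()
  # leaving the image: projected to the border then 2 dva inward
  out <- gazewalk:::apply_border_rules(c(30, 150), c(-20, 150), cfg, 300, 400)
  expect_equal(out[1], 50) # 2 dva = 50 px from the left border
  expect_equal(out[2], 150)
  corner <- gazewalk:::apply_border_rules(c(10, 10), c(-30, -30), cfg, 300, 400)
  expect_true(all(corner >= 0 & corner <= c(400, 300)))
  expect_equal(sqrt(sum(corner^2)), 50, tolerance = 1e-9)
  # inside the buffer: the border-ward displacement component is reflected
  refl <- gazewalk:::apply_border_rules(c(30, 150), c(15, 160), cfg, 300, 400)
  expect_equal(refl, c(45, 160))
})

test_that("simulated walks satisfy the timing, containment and alternation contracts", {
  prof <- fixture_profile()
  sal <- fixture_salience()
  cfg <- sim_config()
  r <- simulate_bcrw(sal, prof, cfg, seed = 7)
  expect_gte(nrow(r$path), 2001)
  expect_gte(max(r$path$time_ms), 10000)
  expect_equal(r$path$x[1], ncol(sal) / 2)
  expect_equal(r$path$y[1], nrow(sal) / 2)
  expect_equal(r$events$kind[1], "saccade")
  expect_true(all(r$events$kind[-1] != r$events$kind[-nrow(r$events)]))
  expect_true(all(r$path$x >= 0 & r$path$x <= ncol(sal)))
  expect_true(all(r$path$y >= 0 & r$path$y <= nrow(sal)))
  expect_true(all(r$fixations$x >= 0 & r$fixations$x <= ncol(sal)))

  r2 <- simulate_bcrw(sal, prof, cfg, seed = 7)
  expect_identical(r$path$x, r2$path$x)
  expect_identical(r$fixations, r2$fixations)

  c1 <- simulate_crw(prof, cfg, dim(sal), seed = 13)
  c2 <- simulate_crw(prof, cfg, dim(sal), seed = 13)
  expect_identical(c1$path$y, c2$path$y)
})

test_that("on a zero salience map saccades are ballistic straight segments", {
  prof <- fixture_profile()
  zero <- structure(matrix(0, 300, 400), px_per_dva = 25)
  checked <- 0
  for (seed in 3:6) {
  r <- simulate_bcrw(zero, prof, sim_config(), seed = seed)
  ev <- r$events[r$events$kind == "saccade", ]
  dt <- attr(r$path, "dt_ms")
  for (i in seq_len(nrow(ev))) {
    idx <- (round(ev$start_ms[i] / dt) + 2):(round(ev$start_ms[i] / dt) + 1 + ev$n_steps[i])
    xs <- r$path$x[idx]; ys <- r$path$y[idx]
    if (length(xs) < 3) next
    # border rules can engage within buffer + one step of an edge
    reach <- 25 + max(sqrt(diff(xs)^2 + diff(ys)^2))
    if (any(xs < reach | xs > 400 - reach | ys < reach | ys > 300 - reach)) next
    dirs <- atan2(diff(ys), diff(xs))
    expect_lt(max(abs(gazewalk:::wrap_angle(diff(dirs)))), 1e-9)
    checked <- checked + 1
  }
  }
  expect_gte(checked, 3)
})

test_that("a persistence-1 profile makes CRW saccades straight lines", {
  prof <- fixture_profile()
  prof$persistence_saccade[] <- 1
  checked <- 0
  for (seed in 5:8) {
  r <- simulate_crw(prof, sim_config(), c(300, 400), seed = seed)
  dt <- attr(r$path, "dt_ms")
  ev <- r$events[r$events$kind == "saccade", ]
  for (i in seq_len(nrow(ev))) {
    idx <- (round(ev$start_ms[i] / dt) + 2):(round(ev$start_ms[i] / dt) + 1 + ev$n_steps[i])
    xs <- r$path$x[idx]; ys <- r$path$y[idx]
    if (length(xs) < 3) next
    reach <- 25 + max(sqrt(diff(xs)^2 + diff(ys)^2))
    if (any(xs < reach | xs > 400 - reach | ys < reach | ys > 300 - reach)) next
    dirs <- atan2(diff(ys), diff(xs))
    expect_lt(max(abs(gazewalk:::wrap_angle(diff(dirs)))), 1e-9)
    checked <- checked + 1
  }
  }
  expect_gte(checked, 3)
})

test_that("low persistence pulls saccades toward a strong single peak", {
  prof <- fixture_profile()
  prof$persistence_saccade[] <- 0.2
  m <- radial_bump_map()
  moved_closer <- 0; total <- 0
  for (seed in 1:3) {
    r <- simulate_bcrw(m, prof, sim_config(), seed = seed)
    dt <- attr(r$path, "dt_ms")
    ev <- r$events[r$events$kind == "saccade", ]
    for (i in seq_len(nrow(ev))) {
      i0 <- round(ev$start_ms[i] / dt) + 1
      i1 <- i0 + ev$n_steps[i]
      d0 <- sqrt((r$path$x[i0] - 260)^2 + (r$path$y[i0] - 120)^2)
      d1 <- sqrt((r$path$x[i1] - 260)^2 + (r$path$y[i1] - 120)^2)
      if (d0 < 100) next # already at the peak; nothing left to climb
      total <- total + 1
      if (d1 < d0) moved_closer <- moved_closer + 1
    }
  }
  expect_gt(moved_closer / total, 0.6)
})

test_that("ensembles pool fixations reproducibly at the expected rate", {
  prof <- fixture_profile()
  sal <- fixture_salience()
  one <- run_ensemble(sal, prof, sim_config(n_runs = 1), seed = 2)
  expect_equal(nrow(one$fixations), nrow(one$results[[1]]$fixations))

  e1 <- run_ensemble(sal, prof, sim_config(n_runs = 3), seed = 9)
  e2 <- run_ensemble(sal, prof, sim_config(n_runs = 3), seed = 9)
  expect_identical(e1$fixations, e2$fixations)

  # expected fixations per run: total_time / (mean fixation + mean saccade)
  cycle <- mean(prof$fixation_durations) + mean(prof$saccade_durations)
  expected <- 3 * 10000 / cycle
  expect_lt(abs(nrow(e1$fixations) - expected) / expected, 0.15)
})

test_that("the BCRW forages: fixations crowd the salient blobs", {
  sc <- fixture_scene()
  sal <- fixture_salience()
  prof <- fixture_profile()
  ens <- run_ensemble(sal, prof, sim_config(n_runs = 12), seed = 9)
  fx <- ens$fixations
  r_px <- sc$blobs$radius_px[1]
  d <- vapply(seq_len(nrow(fx)), function(i) {
    min(sqrt((fx$x[i] - sc$blobs$x)^2 + (fx$y[i] - sc$blobs$y)^2))
  }, 0)
  near_frac <- mean(d <= r_px + 2 * 25) # within 2 dva of a blob
  area_frac <- nrow(sc$blobs) * pi * r_px^2 / prod(dim(sal))
  expect_gte(near_frac, 5 * area_frac)
})

test_that("on a flat map the BCRW degenerates to CRW-like fixation spread", {
  prof <- fixture_profile()
  flat <- structure(matrix(0.5, 300, 400), px_per_dva = 25)
  b <- run_ensemble(flat, prof, sim_config(n_runs = 8), seed = 17, model = "bcrw")
  cw <- run_ensemble(profile = prof, config = sim_config(n_runs = 8), seed = 18,
                     model = "crw", image_size = c(300, 400))
  expect_gt(suppressWarnings(ks.test(b$fixations$x, cw$fixations$x)$p.value), 0.005)
  expect_gt(suppressWarnings(ks.test(b$fixations$y, cw$fixations$y)$p.value), 0.005)
})

test_that("the sweep grid matches the documented parameter grids", {
  g <- sweep_grid()
  expect_equal(g$value[g$parameter == "border_buffer_dva"], c(0.04, 0.4, 1, 2, 4))
  expect_equal(g$value[g$parameter == "border_saccade_distance_dva"], c(0.4, 1, 2, 4, 8))
  expect_equal(g$value[g$parameter == "ior_tau"],
               c(0, 1/50, 1/35, 1/25, 1/17, 1/12, 1/7, 1/3, 1))
  expect_equal(g$value[g$parameter == "ior_radius_dva"], c(0, 1, 2, 4))
})
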
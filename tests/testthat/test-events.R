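# Gaze preprocessing, kinematics, and fixation/saccade detection.

test_that("preprocessing clamps near-border samples and excludes far ones", {
  sz <- c(300, 400)
  p <- scan_path(seq(0, by = 5, length.out = 5),
                 x = c(-10, -30, 50, 410, 200),
                 y = c(50, 50, -20, 320, 150), image_size = sz)
  out <- preprocess_gaze(p)
  expect_equal(out$x[1], 0)          # within 1 dva: moved to the image
  expect_true(out$excluded[2])       # 30 px out: excluded
  expect_equal(out$y[3], 0)
  expect_false(out$excluded[4])      # 10/20 px out: clamped
  expect_equal(out$x[4], 400)
  expect_false(out$excluded[5])

  inside <- scan_path(seq(0, by = 5, length.out = 60),
                      x = runif(60, 10, 390), y = runif(60, 10, 290),
                      image_size = sz)
  pin <- preprocess_gaze(inside)
  expect_equal(pin$x, inside$x)
  expect_equal(pin$y, inside$y)
  expect_false(any(pin$excluded))

  far <- scan_path(c(0, 5, 10), x = c(-100, -100, -100), y = c(0, 0, 0),
                   image_size = sz)
  expect_error(preprocess_gaze(far), "outside")
})

test_that("kinematics matches closed-form oracles", {
  sz <- c(600, 800)
  n <- 200
  t <- seq(0, by = 5, length.out = n)

  still <- scan_path(t, rep(100, n), rep(100, n), sz)
  k0 <- kinematics(still)
  expect_true(all(abs(k0$vel) < 1e-9))
  expect_true(all(abs(k0$acc) < 1e-9))

  # constant velocity: 2 px per 5 ms sample -> 400 px/s
  line <- scan_path(t, 100 + 2 * seq_len(n), rep(100, n), sz)
  kl <- kinematics(line)
  interior <- 10:(n - 10)
  expect_equal(kl$vel[interior], rep(400, length(interior)), tolerance = 1e-9)
  expect_true(all(abs(kl$angvel[interior]) < 1e-9))

  # circle: radius 80 px, period 2 s -> omega = pi rad/s, speed = r*omega
  om <- pi
  ts <- t / 1000
  circ <- scan_path(t, 300 + 80 * cos(om * ts), 300 + 80 * sin(om * ts), sz)
  kc <- kinematics(circ)
  expect_equal(mean(kc$vel[interior]), 80 * om, tolerance = 0.02)
  expect_equal(mean(kc$angvel[interior]), om, tolerance = 0.05)

  expect_error(kinematics(scan_path(c(0, 5, 10), 1:3, 1:3, sz)), "4 samples")
})

test_that("well-separated epochs are segmented exactly", {
  tg <- cbind(x = c(60, 300, 150), y = c(60, 120, 250))
  g <- make_scanpath(oculomotor_spec(noise_sd_dva = 0, persistence_saccade = 1),
                     tg, n_events = 3, image_size = fixture_image_size, seed = 5)
  ev <- detect_events(g$path, seed = 1)
  expect_equal(sum(ev$events$kind == "fixation"), 3)
  expect_equal(sum(ev$events$kind == "saccade"), 2)
  # boundaries within 2 samples of ground truth
  expect_true(all(abs(ev$events$start_index - g$labeling$events$start_index) <= 2))
  expect_true(all(abs(ev$events$end_index - g$labeling$events$end_index) <= 2))
})

test_that("a sub-minimum stationary epoch is absorbed, minimum durations hold", {
  # fixation, saccade, 20 ms pause, saccade, fixation
  seg <- function(n, x0, x1) seq(x0, x1, length.out = n)
  x <- c(rep(50, 60), seg(10, 50, 200), rep(200, 4), seg(10, 200, 350), rep(350, 60))
  y <- rep(150, length(x))
  p <- scan_path(seq(0, by = 5, length.out = length(x)), x, y, c(300, 400))
  ev <- detect_events(p, seed = 1)
  fix <- ev$events[ev$events$kind == "fixation", ]
  expect_equal(nrow(fix), 2)
  expect_true(all(fix$duration_ms >= 25))
  expect_true(all(ev$events$duration_ms[ev$events$kind == "saccade"] >= 10))
})

test_that("degenerate and repeated runs behave predictably", {
  still <- scan_path(seq(0, by = 5, length.out = 80),
                     rep(100, 80), rep(120, 80), c(300, 400))
  ev <- detect_events(still, seed = 3)
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$kind, "fixation")
  expect_equal(ev$events$start_index, 1)
  expect_equal(ev$events$end_index, 80)

  g <- make_scanpath(oculomotor_spec(), fixture_targets(), 5,
                     fixture_image_size, seed = 9)
  e1 <- detect_events(g$path, seed = 11)
  e2 <- detect_events(g$path, seed = 11)
  expect_identical(e1$samples$label, e2$samples$label)
})

test_that("detected events tile the samples and alternate kinds", {
  for (s in 1:3) {
    g <- make_scanpath(oculomotor_spec(), fixture_targets(), 8,
                       fixture_image_size, seed = 100 + s)
    ev <- detect_events(g$path, seed = 1)$events
    expect_true(all(ev$duration_ms[ev$kind == "fixation"] >= 25))
    expect_true(all(ev$duration_ms[ev$kind == "saccade"] >= 10))
    expect_equal(ev$start_index[-1], ev$end_index[-nrow(ev)] + 1L)
    expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
  }
})
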
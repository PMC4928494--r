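# Fixation PDFs, KL divergence, ROC analysis, centroids.

test_that("fixation PDFs have the documented binning geometry", {
  # a fixation at the center of bin (12, 16)
  pdf <- fixation_pdf(cbind(387.5, 287.5), c(600, 800), 25)
  expect_equal(dim(pdf), c(24, 32))
  expect_equal(sum(pdf), 1)
  expect_true(all(pdf > 0))
  peak <- which(unclass(pdf) == max(pdf), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak), c(12, 16))

  # non-integer bin size: shift-task geometry still tiles the image
  pdf2 <- fixation_pdf(cbind(378, 189), c(378, 756), 756 / 32)
  expect_equal(dim(pdf2), c(16, 32))
  expect_equal(sum(pdf2), 1)

  expect_error(fixation_pdf(cbind(numeric(0), numeric(0)), c(600, 800), 25),
               "fixation")
})

test_that("mirror-symmetric fixations give a mirror-symmetric PDF", {
  # positions at pixel centers so mirrored points land on mirrored pixels
  fx <- rbind(c(199.5, 300), c(600.5, 300), c(150.5, 100), c(649.5, 100))
  pdf <- fixation_pdf(fx, c(600, 800), 25)
  expect_lt(max(abs(pdf - pdf[, ncol(pdf):1])), 1e-12)
})

test_that("map PDFs match a brute-force binning oracle", {
  u <- matrix(0.4, 600, 800)
  up <- map_pdf(u, 25)
  expect_equal(as.numeric(up), rep(1 / 768, 768))

  m <- matrix(0, 120, 160)
  m[26:50, 51:75] <- 1 # exactly bin (2, 3) at 25 px/dva
  mp <- map_pdf(m, 25)
  expect_gt(mp[2, 3], 0.999)
  expect_true(all(mp[-(2 + (3 - 1) * 4)] < 1e-10))

  set.seed(8)
  r <- matrix(runif(120 * 160), 120, 160)
  rp <- map_pdf(r, 25)
  oracle <- matrix(0, 4, 6) # floor(120/25) x floor(160/25), remainder absorbed
  for (i in 1:120) {
    for (j in 1:160) {
      bi <- min(floor((i - 0.5) / 25) + 1, 4)
      bj <- min(floor((j - 0.5) / 25) + 1, 6)
      oracle[bi, bj] <- oracle[bi, bj] + r[i, j]
    }
  }
  oracle <- oracle / sum(oracle)
  expect_equal(unclass(rp), oracle, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("KL divergence is symmetric, nonnegative, zero iff equal", {
  set.seed(3)
  fx <- cbind(runif(40, 0, 800), runif(40, 0, 600))
  P <- fixation_pdf(fx, c(600, 800), 25)
  Q <- fixation_pdf(fx + 40, c(600, 800), 25)
  expect_equal(kl_divergence(P, P), 0)
  expect_equal(kl_divergence(P, Q), kl_divergence(Q, P))
  expect_gt(kl_divergence(P, Q), 0)
  expect_error(kl_divergence(P, matrix(0.5, 2, 2)), "shape")

  # two-bin closed form
  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  hand_nats <- sum(log(p / q) * p) + sum(log(q / p) * q)
  hand_bits <- sum(log2(p / q) * p) + sum(log2(q / p) * q)
  expect_equal(kl_divergence(matrix(p), matrix(q), base = exp(1)), hand_nats,
               tolerance = 1e-12)
  expect_equal(kl_divergence(matrix(p), matrix(q)), hand_bits,
               tolerance = 1e-12)
})

test_that("AUROC counts concordant pairs with midranks", {
  expect_equal(gazewalk:::auroc_midrank(c(0.9, 0.8, 0.4), c(0.5, 0.3, 0.2)), 8 / 9)
  expect_equal(gazewalk:::auroc_midrank(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(gazewalk:::auroc_midrank(c(1, 1), c(1, 1)), 0.5)
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  pos <- runif(200); neg <- runif(180)^2
  mine <- gazewalk:::auroc_midrank(pos, neg)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 200), rep(0, 180)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("AUROC separates a predictive map and is monotone-invariant", {
  m <- radial_bump_map()
  set.seed(4)
  # fixations concentrated at the peak: near-perfect discrimination
  fx <- cbind(260 + rnorm(60, 0, 10), 120 + rnorm(60, 0, 10))
  a <- auroc(m, fx, n_random = 500, seed = 2)
  expect_gt(a$value, 0.95)
  m3 <- structure(unclass(m)^3, px_per_dva = 25,
                  class = class(m)) # strictly monotone transform
  a3 <- auroc(m3, fx, n_random = 500, seed = 2)
  expect_equal(a$value, a3$value)
})

test_that("interobserver analysis scores individuals against the group", {
  set.seed(6)
  sz <- c(300, 400)
  conc <- cbind(runif(80, 150, 250), runif(80, 80, 160))
  same <- interobserver_auroc(conc, conc, sz, 25, seed = 1)
  expect_gt(same$value, 0.7)

  unif <- cbind(runif(80, 0, 400), runif(80, 0, 300))
  null <- interobserver_auroc(unif, conc, sz, 25, seed = 1, n_random = 500)
  expect_lt(abs(null$value - 0.5), 0.12)

  left <- cbind(runif(60, 20, 120), runif(60, 50, 250))
  right <- cbind(runif(60, 280, 380), runif(60, 50, 250))
  anti <- interobserver_auroc(left, right, sz, 25, seed = 1)
  expect_lt(anti$value, 0.5)

  cohort <- tibble::tibble(x = c(conc[, 1], unif[, 1]),
                           y = c(conc[, 2], unif[, 2]),
                           observer_id = rep(c("a", "b"), each = 80))
  loo <- interobserver_auroc(cohort, image_size = sz, px_per_dva = 25, seed = 1)
  expect_equal(nrow(loo), 2)
  expect_setequal(loo$observer_id, c("a", "b"))
  single <- cohort[cohort$observer_id == "a", ]
  expect_error(interobserver_auroc(single, image_size = sz), "2 observers")
})

test_that("PDF averaging renormalizes and symmetrizes mirrored inputs", {
  set.seed(9)
  fxl <- cbind(runif(50, 50, 150), runif(50, 100, 200))
  fxr <- cbind(800 - fxl[, 1], fxl[, 2])
  L <- fixation_pdf(fxl, c(600, 800), 25)
  R <- fixation_pdf(fxr, c(600, 800), 25)
  avg <- average_pdf(list(L, R))
  expect_equal(sum(avg), 1)
  expect_lt(max(abs(avg - avg[, ncol(avg):1])), 1e-12)
  same <- average_pdf(list(L, L))
  expect_equal(unclass(same), unclass(L), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(average_pdf(list()), "no PDFs")
})

test_that("centroids equal the mean position with a sane bootstrap CI", {
  corners <- rbind(c(0, 0), c(800, 0), c(0, 600), c(800, 600))
  ct <- centroid(corners, seed = 1)
  expect_equal(ct$x, 400)
  expect_equal(ct$y, 300)

  one <- centroid(cbind(123, 45))
  expect_equal(one$x_lo, 123)
  expect_equal(one$x_hi, 123)

  set.seed(10)
  g <- cbind(rnorm(1000, 350, 40), rnorm(1000, 220, 40))
  cg <- centroid(g, seed = 2)
  se <- 40 / sqrt(1000)
  expect_lt(abs(cg$x - 350), 3 * se)
  expect_lt(abs(cg$y - 220), 3 * se)
  expect_true(cg$x_lo < cg$x && cg$x < cg$x_hi)
})
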
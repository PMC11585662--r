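test_that("tiling_fraction matches hand-computed tiles", {
  st <- spike_train(5, 0, 100)
  expect_equal(tiling_fraction(st, dt = 0.01), 0.020 / 100)  # single tile
  st2 <- spike_train(c(5.000, 5.005), 0, 100)
  expect_equal(tiling_fraction(st2, dt = 0.01), 0.025 / 100) # merged tiles
  st3 <- spike_train(0.002, 0, 100)
  expect_equal(tiling_fraction(st3, dt = 0.01), 0.012 / 100) # boundary clip
  expect_error(tiling_fraction(st, dt = 0), "dt")
  expect_equal(tiling_fraction(spike_train(numeric(0), 0, 1), 0.01), 0)
})

test_that("tiling_fraction agrees with the interval-merge oracle", {
  set.seed(13)
  for (i in 1:25) {
    tr <- poisson_train(runif(1, 0.5, 20), 30)
    if (!n_spikes(tr)) next
    expect_equal(tiling_fraction(tr, 0.01),
                 tiling_brute(tr$times, 0.01, 0, 30), tolerance = 1e-12)
  }
})

test_that("sttc matches the worked example and the brute-force oracle", {
  a <- spike_train(c(1, 2, 3), 0, 10, "a")
  b <- spike_train(c(1.004, 2.2, 2.996), 0, 10, "b")
  # hand values: P_A = P_B = 2/3, T_A = T_B = 0.006
  expect_equal(tiled_proportion(a, b, 0.01), 2 / 3)
  expect_equal(tiling_fraction(a, 0.01), 0.006)
  hand <- 0.5 * 2 * ((2 / 3 - 0.006) / (1 - (2 / 3) * 0.006))
  expect_equal(sttc(a, b, 0.01), hand, tolerance = 1e-12)
  expect_equal(sttc(a, b, 0.01), sttc_brute(a, b, 0.01), tolerance = 1e-12)
})

test_that("sttc identities: self-coefficient 1, symmetry, empty rejection", {
  set.seed(17)
  for (i in 1:10) {
    a <- poisson_train(runif(1, 0.5, 5), 20, "a")
    b <- poisson_train(runif(1, 0.5, 5), 20, "b")
    if (!n_spikes(a) || !n_spikes(b)) next
    expect_identical(sttc(a, a), 1)
    expect_identical(sttc(a, b), sttc(b, a))
  }
  empty <- spike_train(numeric(0), 0, 20)
  full <- spike_train(1:5, 0, 20)
  expect_error(sttc(empty, full), "empty")
})

test_that("sttc is invariant under a common time shift", {
  set.seed(19)
  a <- poisson_train(2, 30, "a")
  b <- poisson_train(2, 30, "b")
  s0 <- sttc(a, b)
  sh <- 7.3
  a2 <- spike_train(a$times + sh, sh, 30 + sh, "a")
  b2 <- spike_train(b$times + sh, sh, 30 + sh, "b")
  expect_equal(sttc(a2, b2), s0, tolerance = 1e-12)
})

test_that("cross_correlogram recovers a planted 2 ms shift", {
  set.seed(23)
  t <- sort(runif(360, 0, 180))
  a <- spike_train(t, 0, 180, "a")
  b <- spike_train(pmin(t + 0.002, 180), 0, 180, "b")
  cg <- cross_correlogram(a, b, bin = 5e-4, half_window = 0.05)
  expect_equal(cg$centers[which.max(cg$prob)], 0.002)
  expect_equal(sum(cg$prob), 1)
  expect_true(all(cg$prob >= 0))
  # against the all-pairs oracle
  br <- correlogram_brute(a, b)
  expect_identical(cg$counts, br$counts)
  expect_equal(cg$centers, br$centers)
})

test_that("cross_correlogram degenerate cases", {
  a <- spike_train(c(1, 2, 3), 0, 10, "a")
  self <- cross_correlogram(a, a)
  expect_equal(self$centers[which.max(self$prob)], 0)
  far <- cross_correlogram(a, spike_train(9, 0, 10, "b"))
  expect_true(far$empty)
  expect_error(cross_correlogram(a, a, bin = -1), "bin")
  expect_error(cross_correlogram(a, a, bin = 0.1, half_window = 0.05),
               "half_window")
})

test_that("correlogram mirror symmetry: cg(a,b) reversed equals cg(b,a)", {
  set.seed(29)
  a <- poisson_train(3, 60, "a")
  b <- poisson_train(3, 60, "b")
  ab <- cross_correlogram(a, b)
  ba <- cross_correlogram(b, a)
  expect_identical(rev(ab$counts), ba$counts)
})

test_that("significant_delay applies the mean + 5 SD gate", {
  # delta-like histogram: one bin holds 0.9 of the mass over 201 bins
  k <- 201L
  counts <- rep(1L, k)
  counts[140L] <- as.integer(round(0.9 * 200 / 0.1))  # 1800 of 2000
  cg <- structure(list(centers = seq(-100, 100) * 5e-4,
                       prob = counts / sum(counts), counts = counts,
                       total = sum(counts), bin = 5e-4, half_window = 0.05,
                       empty = FALSE), class = "correlogram")
  p <- cg$prob
  expect_gt(max(p), mean(p) + 5 * sd(p))  # oracle on the built histogram
  res <- significant_delay(cg, sig_sd = 5)
  expect_true(res$significant)
  expect_equal(res$delay_s, cg$centers[140L])
})

test_that("uniform and empty correlograms are never significant", {
  a <- spike_train(c(1, 2, 3), 0, 10, "a")
  far <- cross_correlogram(a, spike_train(9, 0, 10, "b"))
  r0 <- significant_delay(far)
  expect_false(r0$significant)
  expect_identical(r0$reason, "empty")
  k <- 201L
  cg <- structure(list(centers = seq(-100, 100) * 5e-4,
                       prob = rep(1 / k, k), counts = rep(2L, k),
                       total = 2L * k, bin = 5e-4, half_window = 0.05,
                       empty = FALSE), class = "correlogram")
  ru <- significant_delay(cg)
  expect_false(ru$significant)
  expect_identical(ru$reason, "uniform")
})

test_that("tied maxima resolve to the smallest |delay|, positive first", {
  k <- 201L
  counts <- rep(0L, k)
  counts[c(101L - 4L, 101L + 4L)] <- 50L   # ties at -2 ms and +2 ms
  counts[101L + 30L] <- 1L
  cg <- structure(list(centers = seq(-100, 100) * 5e-4,
                       prob = counts / sum(counts), counts = counts,
                       total = sum(counts), bin = 5e-4, half_window = 0.05,
                       empty = FALSE), class = "correlogram")
  res <- significant_delay(cg)
  expect_true(res$significant)
  expect_equal(res$delay_s, 0.002)   # positive member of the tie
})

test_that("propagation_speed follows d / |t|", {
  expect_equal(propagation_speed(300e-6, 1e-3), 0.3)
  expect_equal(propagation_speed(600e-6, 2e-3), 0.3)
  expect_equal(propagation_speed(600e-6, -2e-3), 0.3)  # sign-insensitive
  expect_true(is.na(propagation_speed(300e-6, 0)))
  expect_error(propagation_speed(-1, 1e-3), "distance")
})

test_that("pairwise_table composes the stages on a shifted-copy pair", {
  set.seed(31)
  t <- sort(runif(360, 0, 180))
  rec <- quick_recording(list(R2C4 = t, R7C4 = pmin(t + 0.002, 180)),
                         duration = 180)
  pw <- pairwise_table(rec)
  # only 2 active electrodes -> one row
  expect_equal(nrow(pw), 1L)
  expect_true(pw$significant)
  expect_equal(pw$delay_s, 0.002)
  expect_equal(pw$distance_pitch, 5)
  expect_equal(pw$speed_mps, 5 * 300e-6 / 0.002)
  expect_gt(pw$sttc, 0.9)
})

test_that("pairwise_table excludes low-activity electrodes and warns when empty", {
  rec <- quick_recording(list(R1C1 = c(1, 2), R2C2 = c(3, 4)), duration = 10)
  expect_warning(pw <- pairwise_table(rec), "fewer than 2 active")
  expect_equal(nrow(pw), 0L)
  expect_true("R1C1" %in% attr(pw, "excluded"))
  # an all-empty recording behaves the same
  rec0 <- quick_recording(list(), duration = 10)
  expect_warning(pw0 <- pairwise_table(rec0), "fewer than 2 active")
  expect_equal(nrow(pw0), 0L)
})
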
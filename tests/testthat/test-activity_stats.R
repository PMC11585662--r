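test_that("basal_metrics counts spikes, ISIs and bursts", {
  # regular 1 Hz train: 60 spikes, mean ISI 1 s, no bursts at max_isi 0.1
  reg <- spike_train(seq(0.5, 59.5, by = 1), 0, 60)
  m <- basal_metrics(reg, burst_max_isi = 0.1, burst_min_spikes = 5)
  expect_equal(m$n_spikes, 60L)
  expect_equal(m$mean_isi_s, 1)
  expect_equal(m$burst_frequency_hz, 0)
  # 3 bursts of 5 spikes at 10 ms ISI -> 3 / 60 = 0.05 Hz
  bursts <- c(outer(0:4 * 0.01, c(10, 30, 50), "+"))
  bt <- spike_train(sort(bursts), 0, 60)
  mb <- basal_metrics(bt)
  expect_equal(mb$n_bursts, 3L)
  expect_equal(mb$burst_frequency_hz, 0.05)
  # empty train: count 0, undefined ISI, zero burst rate
  e <- basal_metrics(spike_train(numeric(0), 0, 60))
  expect_equal(e$n_spikes, 0L)
  expect_true(is.na(e$mean_isi_s))
  expect_equal(e$burst_frequency_hz, 0)
  # a run of 4 spikes does not reach the 5-spike burst floor
  short <- spike_train(c(1, 1.01, 1.02, 1.03), 0, 60)
  expect_equal(basal_metrics(short)$n_bursts, 0L)
})

test_that("mean_firing_rate averages over all electrodes", {
  set.seed(71)
  n_per <- 180L
  trains <- lapply(sprintf("R%dC%d", rep(1:8, each = 8), rep(1:8, 8)),
                   function(e) sort(runif(n_per, 0, 180)))
  names(trains) <- sprintf("R%dC%d", rep(1:8, each = 8), rep(1:8, 8))
  rec <- quick_recording(trains, duration = 180)
  expect_equal(mean_firing_rate(rec), 1)      # 11520 spikes / (64 x 180)
  rec1 <- quick_recording(list(R1C1 = sort(runif(180, 0, 180))),
                          duration = 180)
  expect_equal(mean_firing_rate(rec1), 1 / 64)
  rec0 <- quick_recording(list(), duration = 10)
  expect_equal(mean_firing_rate(rec0), 0)
})

test_that("batch_normalize divides by batch means and is idempotent", {
  expect_equal(batch_normalize(c(2, 4), c("b1", "b1")), c(2 / 3, 4 / 3))
  expect_equal(batch_normalize(c(1, 1, 5, 5), c("a", "a", "b", "b")),
               rep(1, 4))
  expect_error(batch_normalize(c(-1, 1), c("a", "a")), "zero mean")
  set.seed(73)
  v <- rexp(30) + 0.1
  b <- rep(c("x", "y", "z"), each = 10)
  once <- batch_normalize(v, b)
  expect_equal(batch_normalize(once, b), once, tolerance = 1e-12)
  expect_equal(as.numeric(tapply(once, b, mean)), rep(1, 3),
               tolerance = 1e-12)
})

test_that("iqr_outlier_filter applies the type-7 fences", {
  # {1,2,3,4,100}: Q1 = 2, Q3 = 4, fences [-1, 7] under type 7
  r <- iqr_outlier_filter(c(1, 2, 3, 4, 100))
  expect_equal(r$removed, 100)
  expect_equal(r$kept, c(1, 2, 3, 4))
  expect_equal(r$fences, c(-1, 7))
  # zero IQR keeps equal values
  r2 <- iqr_outlier_filter(c(5, 5, 5, 5))
  expect_equal(r2$kept, c(5, 5, 5, 5))
  expect_length(r2$removed, 0L)
  # all within fences -> identity
  r3 <- iqr_outlier_filter(c(1, 2, 3, 4, 5))
  expect_equal(r3$kept, c(1, 2, 3, 4, 5))
  expect_warning(r4 <- iqr_outlier_filter(c(1, 2)), "fewer than 4")
  expect_equal(r4$kept, c(1, 2))
})

test_that("iqr filtering is single-pass with fences fixed on the input", {
  set.seed(79)
  for (i in 1:10) {
    v <- c(rnorm(20), rnorm(2, 0, 10))
    r <- iqr_outlier_filter(v)
    # fences computed once on the input determine the kept set exactly
    expect_setequal(r$kept, v[v >= r$fences[1] & v <= r$fences[2]])
    # re-filtering only ever shrinks: recomputed fences may tighten, so
    # the filter is documented as single-pass rather than a fixed point
    again <- iqr_outlier_filter(r$kept)
    expect_true(all(again$kept %in% r$kept))
  }
})

test_that("routed tests follow the stated decision tree", {
  set.seed(83)
  g_norm <- list(a = rnorm(20, 0, 1), b = rnorm(20, 0.2, 1))
  r <- hypothesis_tests(g_norm)
  expect_identical(r$route, "parametric")
  expect_match(r$omnibus$method, "Welch")
  g_skew <- list(a = rexp(20)^3, b = rexp(20)^3)
  r2 <- hypothesis_tests(g_skew)
  expect_identical(r2$route, "nonparametric")
  expect_match(r2$omnibus$method, "Wilcoxon")
  # > 2 groups route to ANOVA + Tukey or Kruskal-Wallis + Dunn
  g3 <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15, 1))
  r3 <- hypothesis_tests(g3)
  expect_identical(r3$route, "parametric")
  expect_match(r3$omnibus$method, "ANOVA")
  expect_equal(nrow(r3$pairwise), 3L)
  g3s <- lapply(g3, function(x) rexp(15)^3)
  r4 <- hypothesis_tests(g3s)
  expect_match(r4$omnibus$method, "Kruskal")
  expect_named(r4$pairwise,
               c("group1", "group2", "statistic", "p", "p_adj", "stars"))
  # tiny groups force the nonparametric route with a warning
  expect_warning(r5 <- hypothesis_tests(list(a = c(1, 2), b = c(5, 6))),
                 "nonparametric")
  expect_identical(r5$route, "nonparametric")
})

test_that("exact Wilcoxon and identity fixtures", {
  # {1,2,3,4} vs {10,11,12,13}: exact two-sided p = 2/70 (the two most
  # extreme of the 70 equally likely rank assignments)
  r <- hypothesis_tests(list(a = c(1, 2, 3, 4), b = c(10, 11, 12, 13)),
                        route = "nonparametric")
  expect_match(r$omnibus$method, "Wilcoxon")
  expect_equal(r$omnibus$p, 2 / 70, tolerance = 1e-12)
  # identical groups: no shift, p = 1
  r2 <- hypothesis_tests(list(a = c(1, 2, 3), b = c(1, 2, 3)),
                         route = "nonparametric")
  expect_match(r2$omnibus$method, "Wilcoxon")
  expect_equal(r2$omnibus$p, 1, tolerance = 1e-9)
})

test_that("BH adjustment matches the step-up formula", {
  p <- c(0.01, 0.02, 0.03)
  # step-up: p_(i) * m / i, cummin from the largest
  expect_equal(p.adjust(p, "BH"), c(0.03, 0.03, 0.03))
  expect_equal(stats::p.adjust(c(0.01, 0.04, 0.03, 0.005), "BH"),
               {
                 pp <- c(0.01, 0.04, 0.03, 0.005)
                 o <- order(pp); m <- length(pp)
                 adj <- pmin(1, rev(cummin(rev(pp[o] * m / seq_len(m)))))
                 adj[order(o)]
               })
  d <- dunn_test(c(1, 2, 3, 10, 11, 12, 20, 21, 22),
                 rep(c("a", "b", "c"), each = 3))
  expect_equal(d$p_adj, p.adjust(d$p, "BH"))
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(89)
  a <- rexp(12); b <- rexp(12) + 0.5; c <- rexp(12) + 1
  f <- function(x) exp(3 * x) + 5   # strictly monotone
  v <- c(a, b, c); g <- rep(1:3, each = 12)
  d1 <- dunn_test(v, g); d2 <- dunn_test(f(v), g)
  expect_equal(d1$z, d2$z, tolerance = 1e-12)
  expect_equal(d1$p_adj, d2$p_adj, tolerance = 1e-12)
})

test_that("significance stars follow the printed convention", {
  expect_equal(p_stars(c(0.04, 0.009, 0.0009, 0.00009, 0.2)),
               c("*", "**", "***", "****", "ns"))
})
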
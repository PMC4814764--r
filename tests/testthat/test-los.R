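# delay profiles around the line of synchrony and leader-follower measures

test_that("profile normalization and edge cases are per-diagonal", {
  # identical constant series: fully recurrent plot, RR_tau = 1 everywhere
  crp <- build_crp(rep(1L, 30), rep(1L, 30))
  prof <- los_profile(crp, 10)
  expect_true(all(prof$rr == 1))

  # identical but gappy series: maximal at tau = 0
  g <- rep(c(1L, 1L, 0L), 12)
  prof <- los_profile(build_crp(g, g), 8)
  m <- los_measures(prof)
  expect_equal(m$tau_peak, 0L)
  expect_equal(m$pct_sync, 100 * mean(g > 0))

  # no recurrence at all
  prof <- los_profile(build_crp(rep(0L, 20), rep(0L, 20)), 5)
  expect_true(all(prof$rr == 0))
  m <- los_measures(prof)
  expect_true(is.na(m$tau_peak))
  expect_true(is.na(m$q_los))
  expect_equal(m$rr_peak, 0)

  expect_error(los_profile(build_crp(rep(1L, 5), rep(1L, 5)), 5), "window")
  expect_error(los_profile(structure(matrix(1L, 2, 3),
                                     class = c("crp", "matrix")), 1),
               "square")
})

test_that("profile counts equal a brute-force double loop", {
  set.seed(711)
  for (rep in 1:15) {
    crp <- build_crp(random_tiers(25), random_tiers(25))
    got <- los_profile(crp, 10)
    want <- oracle_profile(unclass(crp), 10)
    expect_equal(got$count, want$count)
    expect_equal(got$rr, want$rr)
  }
})

test_that("a delayed copy of the gesture stream is detected at +k", {
  set.seed(812)
  n <- 200
  g <- as.integer(to_tiers(sample(0:6, n, replace = TRUE,
                                  prob = c(0.5, rep(0.5 / 6, 6)))))
  for (k in c(-30, -7, 0, 5, 22)) {
    s <- integer(n)
    if (k >= 0) s[(k + 1):n] <- g[1:(n - k)] else s[1:(n + k)] <- g[(1 - k):n]
    m <- los_measures(los_profile(build_crp(g, s), 40))
    expect_equal(m$tau_peak, k)
  }
})

test_that("swapping the streams mirrors the profile", {
  set.seed(913)
  for (rep in 1:10) {
    g <- random_tiers(60); s <- random_tiers(60)
    a <- los_measures(los_profile(build_crp(g, s), 20))
    b <- los_measures(los_profile(build_crp(s, g), 20))
    expect_equal(a$pct_sync, b$pct_sync)
    expect_equal(a$rr_peak, b$rr_peak)
    if (!is.na(a$tau_peak) && a$tau_peak != 0) {
      expect_equal(b$tau_peak, -a$tau_peak)
    }
    if (!is.na(a$q_los) && !is.na(b$q_los) && a$q_los > 0) {
      expect_equal(b$q_los, 1 / a$q_los)
    }
  }
})

test_that("q_los takes sides correctly and ties break toward the LOS", {
  # all recurrence strictly on the gesture-leading side (tau = +5):
  # empty speech-leading side gives q_los = 0
  g <- c(rep(1L, 3), rep(0L, 17))
  s <- c(rep(0L, 5), rep(1L, 3), rep(0L, 12))
  m <- los_measures(los_profile(build_crp(g, s), 10))
  expect_equal(m$tau_peak, 5L)
  expect_equal(m$q_los, 0)
  # mirrored: empty gesture-leading side leaves q_los undefined
  m2 <- los_measures(los_profile(build_crp(s, g), 10))
  expect_true(is.na(m2$q_los))
  expect_equal(m2$tau_peak, -5L)

  # symmetric profile: q_los exactly 1, peak at the LOS
  g <- c(0L, 1L, 1L, 1L, 0L, 0L, 2L, 2L, 2L, 0L)
  m3 <- los_measures(los_profile(build_crp(g, g), 4))
  expect_equal(m3$q_los, 1)
  expect_equal(m3$tau_peak, 0L)

  # equal-count tie off the LOS resolves to the positive delay
  prof <- structure(list(tau = -2:2, count = c(0L, 3L, 0L, 3L, 0L),
                         rr = c(0, 3, 0, 3, 0) / c(8, 9, 10, 9, 8),
                         window_s = 2L, n = 10L), class = "los_profile")
  expect_equal(los_measures(prof)$tau_peak, 1L)
})

test_that("rr_peak permutation screen separates coupling from chance", {
  # strongly coupled pair: shifted copy, lag 5, no noise
  set.seed(121)
  g <- as.integer(to_tiers(unlist(lapply(1:30, function(i) {
    c(rep(sample(c(1:3, 0), 1), sample(3:8, 1)), rep(0L, sample(1:4, 1)))
  }))))
  n <- length(g)
  s <- c(rep(0L, 5), g[1:(n - 5)])
  res <- rr_peak_test(g, s, window_s = 30, n_perm = 300, seed = 42)
  expect_lte(res$p_value, 0.01)
  expect_equal(res$observed,
               max(los_profile(build_crp(g, s), 30)$rr))

  # reproducible bit-exactly given the seed
  res2 <- rr_peak_test(g, s, window_s = 30, n_perm = 300, seed = 42)
  expect_identical(res, res2)

  # zero observed peak: no permutation can be beaten downward
  res0 <- rr_peak_test(rep(0L, 50), rep(1L, 50), window_s = 10, n_perm = 50,
                       seed = 1)
  expect_equal(res0$p_value, 1)

  # second-shuffle null is available and also flags the coupled pair
  ress <- rr_peak_test(g, s, window_s = 30, n_perm = 200, seed = 7,
                       null = "second_shuffle")
  expect_lte(ress$p_value, 0.01)
})

test_that("rr_peak p-values are roughly uniform for uncoupled streams", {
  set.seed(232)
  ps <- replicate(200, {
    g <- random_tiers(80, p_zero = 0.5)
    s <- random_tiers(80, p_zero = 0.5)
    rr_peak_test(g, s, window_s = 10, n_perm = 60)$p_value
  })
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})

test_that("episode shuffling preserves durations and level composition", {
  set.seed(343)
  x <- c(0L, 0L, 1L, 1L, 1L, 0L, 2L, 2L, 0L, 0L, 0L, 3L)
  for (i in 1:20) {
    y <- shuffle_episodes(x)
    expect_equal(sort(y), sort(x))
    # nonzero run lengths survive as a multiset
    rx <- rle(x); ry <- rle(y)
    expect_equal(sort(ry$lengths[ry$values > 0]),
                 sort(rx$lengths[rx$values > 0]))
  }
})
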
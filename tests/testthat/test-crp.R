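# tier-matched cross-recurrence plots and anisotropic measures

test_that("build_crp marks exactly the same-tier, leveled cells", {
  full <- build_crp(c(1, 1, 1), c(1, 1, 1))
  expect_true(all(full == 1L))
  expect_equal(crqa_measures(full)$rr, 1)

  expect_true(all(build_crp(c(1, 1), c(2, 2)) == 0L))

  # hand-enumerated 3x3 case: matches at (gesture 1, speech 2) tier 1 and
  # (gesture 3, speech 1) tier 2; the shared zeros never recur
  m <- build_crp(c(1, 0, 2), c(2, 1, 0))
  idx <- which(unclass(m) > 0, arr.ind = TRUE)
  expect_equal(unname(idx[order(idx[, 1]), , drop = FALSE]),
               matrix(c(1L, 3L, 2L, 1L), 2, 2))
  expect_equal(m[1, 2], 1L)
  expect_equal(m[3, 1], 2L)

  expect_error(build_crp(c(1, 2), c(1, 2, 3)), "length")
  expect_error(build_crp(c(1, 4), c(1, 1)), "0..3")
})

test_that("extract_lines returns the maximal runs, tier-labeled", {
  # single fully recurrent column
  g <- rep(2L, 5); s <- c(0L, 2L, 0L, 0L, 0L)
  crp <- build_crp(g, s)
  v <- extract_lines(crp, "vertical", min_line = 2)
  expect_equal(nrow(v), 1)
  expect_equal(v$anchor, 2L)
  expect_equal(v$length, 5L)
  expect_equal(v$tier, 2L)
  expect_equal(nrow(extract_lines(crp, "horizontal", min_line = 2)), 0)
  # each row contributes an isolated horizontal point at min_line = 1
  h <- extract_lines(crp, "horizontal", min_line = 1)
  expect_equal(nrow(h), 5)
  expect_true(all(h$length == 1L))

  empty <- build_crp(rep(0L, 4), rep(0L, 4))
  expect_equal(nrow(extract_lines(empty, "vertical")), 0)

  # oracle equivalence on random plots
  set.seed(202)
  for (rep in 1:25) {
    m <- build_crp(random_tiers(8), random_tiers(8))
    for (o in c("vertical", "horizontal")) {
      got <- extract_lines(m, o, min_line = 1)
      want <- oracle_lines(unclass(m), o, min_line = 1)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got[order(got$anchor, got$start), ],
                   want[order(want$anchor, want$start), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("global measures match their definitions on edge plots", {
  full <- build_crp(rep(1L, 3), rep(1L, 3))
  m <- crqa_measures(full)
  expect_equal(m[c("rr", "lam_v", "lam_h", "tt_v", "tt_h", "maxl_v", "maxl_h")],
               list(rr = 1, lam_v = 1, lam_h = 1, tt_v = 3, tt_h = 3,
                    maxl_v = 3, maxl_h = 3))

  # a single isolated recurrent point counts for RR and MaxL only
  iso <- build_crp(c(1L, 0L, 0L), c(0L, 1L, 0L))
  m <- crqa_measures(iso)
  expect_equal(m$rr, 1 / 9)
  expect_equal(m$lam_v, 0)
  expect_equal(m$lam_h, 0)
  expect_equal(m$tt_v, 0)
  expect_equal(m$tt_h, 0)
  expect_equal(m$maxl_v, 1)
  expect_equal(m$maxl_h, 1)

  zero <- crqa_measures(build_crp(rep(0L, 3), rep(0L, 3)))
  expect_true(all(unlist(zero[1:7]) == 0))
})

test_that("all global measures equal a brute-force recomputation", {
  set.seed(303)
  for (rep in 1:30) {
    crp <- build_crp(random_tiers(12), random_tiers(12))
    got <- crqa_measures(crp)
    want <- oracle_measures(unclass(crp))
    expect_equal(got[names(want)], want)
  }
})

test_that("tier measures split the plot and stay additive", {
  # 10 tier-1 cells in vertical lines, 10 tier-2 cells: 2 speech seconds of
  # each tier against 5 matching gesture seconds
  g <- c(rep(1L, 5), rep(2L, 5))
  s <- c(1L, 1L, 2L, 2L, rep(0L, 6))
  crp <- build_crp(g, s)
  t1 <- tier_measures(crp, 1)
  expect_equal(t1$pct_rr, 50)
  expect_equal(t1$lam_v, 0.5)
  expect_equal(t1$tt_v, 5)
  expect_equal(t1$maxl_v, 5)

  # absent tier
  t3 <- tier_measures(crp, 3)
  expect_equal(unlist(t3[c("pct_rr", "lam_v", "lam_h", "tt_v", "tt_h",
                           "maxl_v", "maxl_h")]),
               c(pct_rr = 0, lam_v = 0, lam_h = 0, tt_v = 0, tt_h = 0,
                 maxl_v = 0, maxl_h = 0))

  # additivity across tiers, exactly, on random plots
  set.seed(404)
  for (rep in 1:20) {
    crp <- build_crp(random_tiers(20), random_tiers(20))
    if (sum(crp > 0) == 0) next
    tm <- lapply(1:3, function(t) tier_measures(crp, t))
    glob <- crqa_measures(crp)
    expect_equal(sum(vapply(tm, `[[`, numeric(1), "pct_rr")), 100)
    expect_equal(sum(vapply(tm, `[[`, numeric(1), "lam_v")), glob$lam_v)
    expect_equal(sum(vapply(tm, `[[`, numeric(1), "lam_h")), glob$lam_h)
  }
})

test_that("transposing the plot swaps the anisotropic measures", {
  set.seed(505)
  for (rep in 1:20) {
    g <- random_tiers(15); s <- random_tiers(15)
    a <- build_crp(g, s)
    b <- build_crp(s, g)
    expect_identical(unclass(b), t(unclass(a)))
    ma <- crqa_measures(a); mb <- crqa_measures(b)
    expect_equal(ma$rr, mb$rr)
    expect_equal(ma$lam_v, mb$lam_h)
    expect_equal(ma$tt_v, mb$tt_h)
    expect_equal(ma$maxl_v, mb$maxl_h)
    expect_equal(ma$lam_h, mb$lam_v)
  }
})

test_that("adding recurrence is monotone for RR and MaxL", {
  set.seed(606)
  for (rep in 1:10) {
    g <- random_tiers(15); s <- random_tiers(15)
    crp <- build_crp(g, s)
    m0 <- crqa_measures(crp)
    # force one extra matching second into the gesture stream
    zeros <- which(g == 0 & s != 0)
    if (length(zeros) == 0) next
    g2 <- g; i <- zeros[1]; g2[i] <- s[i]
    m1 <- crqa_measures(build_crp(g2, s))
    expect_gte(m1$rr, m0$rr)
    expect_gte(m1$maxl_v, m0$maxl_v)
    expect_gte(m1$maxl_h, m0$maxl_h)
  }
})

test_that("asymmetry scores implement the relative-difference formulas", {
  sc <- asymmetry_scores(list(lam_v = 0.669, lam_h = 0.595,
                              tt_v = 7.6, tt_h = 3.2,
                              maxl_v = 21, maxl_h = 7))
  expect_equal(round(sc$vh_tt, 2), 0.41)
  expect_equal(round(sc$vh_maxl, 2), 0.50)
  expect_equal(round(sc$vh_lam, 3), 0.074)

  # equal operands give 0; a 0-vs-positive contrast gives +/-1
  expect_equal(asymmetry_scores(list(lam_v = 0.5, lam_h = 0.5, tt_v = 4,
                                     tt_h = 4, maxl_v = 9, maxl_h = 9)),
               list(vh_lam = 0, vh_tt = 0, vh_maxl = 0))
  one <- asymmetry_scores(list(lam_v = 0.1, lam_h = 0, tt_v = 3, tt_h = 0,
                               maxl_v = 3, maxl_h = 1))
  expect_equal(one$vh_tt, 1)
  # both operands 0: undefined, encoded as missing
  none <- asymmetry_scores(list(lam_v = 0, lam_h = 0, tt_v = 0, tt_h = 0,
                                maxl_v = 0, maxl_h = 0))
  expect_true(is.na(none$vh_tt) && is.na(none$vh_maxl))
  expect_equal(none$vh_lam, 0)
})

test_that("crp export round-trips in dense and sparse form", {
  crp <- build_crp(c(1L, 0L, 2L, 2L), c(2L, 1L, 0L, 2L))
  dense <- withr::local_tempfile(fileext = ".csv")
  write_crp(crp, dense)
  back <- as.matrix(utils::read.csv(dense, header = FALSE))
  expect_equal(unname(back), unclass(crp), ignore_attr = TRUE)
  sp <- withr::local_tempfile(fileext = ".csv")
  write_crp(crp, sp, sparse = TRUE)
  trip <- utils::read.csv(sp)
  expect_equal(nrow(trip), sum(crp > 0))
  expect_equal(crp[cbind(trip$i, trip$j)], trip$tier)
})
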
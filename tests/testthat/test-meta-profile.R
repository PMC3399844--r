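test_that("the toy two-level profile is summarized exactly", {
  mp <- build_meta_profile(c(1, 1, 1, 5, 5, 5), "toy",
                           min_side_fraction = 0.1)
  expect_equal(mp$min, 1)
  expect_equal(mp$max, 5)
  expect_equal(mp$threshold, 3)
  expect_length(mp$low_side, 3)
  expect_length(mp$high_side, 3)
  expect_equal(dynamic_range(mp), 4)
})

test_that("a constant profile collapses every summary to the one value", {
  mp <- build_meta_profile(rep(7, 50), "flat")
  expect_equal(mp$min, 7)
  expect_equal(mp$max, 7)
  expect_equal(mp$threshold, 7)
  expect_equal(mp$trimmed_low, 7)
  expect_equal(mp$trimmed_high, 7)
  expect_equal(dynamic_range(mp), 0)
  expect_equal(dynamic_range(mp, trimmed = TRUE), 0)
})

test_that("trimmed bounds match a hand-written quantile interpolation", {
  set.seed(402)
  v <- runif(1000, 0, 10)
  mp <- build_meta_profile(v, "unif", trim_fraction = 0.005)
  expect_equal(mp$trimmed_low, quantile_oracle(v, 0.005))
  expect_equal(mp$trimmed_high, quantile_oracle(v, 0.995))
  # a 0.5% trim on uniform [0, 10] keeps close to 9.9 of the spread
  expect_equal(dynamic_range(mp, trimmed = TRUE), 9.9, tolerance = 0.02)
  expect_lte(dynamic_range(mp, trimmed = TRUE), dynamic_range(mp))
})

test_that("trimmed range never exceeds the untrimmed range", {
  set.seed(403)
  for (i in 1:20) {
    v <- rnorm(sample(20:500, 1), 6, runif(1, 0.2, 3))
    mp <- build_meta_profile(v, "p")
    expect_lte(dynamic_range(mp, trimmed = TRUE), dynamic_range(mp))
  }
})

test_that("percentiles hit the -100/0/+100 anchors exactly and are monotone", {
  set.seed(404)
  profiles <- list(
    build_meta_profile(rnorm(500, 6, 1), "unimodal"),
    build_meta_profile(c(rnorm(300, 4, 0.5), rnorm(200, 10, 0.5)), "bimodal"),
    build_meta_profile(runif(400, 2, 9), "ramp"),
    build_meta_profile(c(1, 1, 1, 5, 5, 5), "toy", min_side_fraction = 0.1)
  )
  for (mp in profiles) {
    expect_identical(percentile_of(mp, mp$min), -100)
    expect_identical(percentile_of(mp, mp$threshold), 0)
    expect_identical(percentile_of(mp, mp$max), 100)
    expect_equal(percentile_of(mp, mp$min - 1), -100)   # clamp below
    expect_equal(percentile_of(mp, mp$max + 1), 100)    # clamp above
    q <- sort(runif(500, mp$min - 0.5, mp$max + 0.5))
    p <- percentile_of(mp, q)
    expect_false(is.unsorted(p))
    expect_true(all(p >= -100 & p <= 100))
  }
})

test_that("rank percentiles equal the anchor-counting oracle, ties included", {
  set.seed(405)
  for (i in 1:15) {
    v <- round(c(rnorm(60, 4, 0.6), rnorm(40, 9, 0.6)), 1)  # duplicates
    mp <- build_meta_profile(v, "tied")
    row <- sort(v)
    # the counting oracle is exact at reference members and the threshold
    for (q in c(sample(v, 10), mp$threshold)) {
      expect_equal(percentile_of(mp, q),
                   rank_percentile_oracle(row, mp$threshold, q),
                   tolerance = 1e-12,
                   info = sprintf("i=%d q=%.3f", i, q))
    }
  }
})

test_that("toy profile percentile of a high-side member follows its rank", {
  mp <- build_meta_profile(c(1, 1, 1, 5, 5, 5), "toy",
                           min_side_fraction = 0.1)
  # 5 is the top (all three) of the high side -> 100 * 3/3
  expect_equal(percentile_of(mp, 5), 100)
  expect_equal(percentile_of(mp, 4), 50)    # halfway to the only anchor
  expect_equal(percentile_of(mp, 2), -50)   # mirrored on the low side
})

test_that("intensity-linear percentiles are exposed as an option", {
  mp <- build_meta_profile(c(rep(2, 5), 4, rep(8, 4)), "lin")
  thr <- mp$threshold
  v <- thr + 0.25 * (mp$max - thr)
  expect_equal(percentile_of(mp, v, method = "linear"), 25)
  expect_equal(percentile_of(mp, mp$min, method = "linear"), -100)
  expect_equal(percentile_of(mp, mp$max, method = "linear"), 100)
})

test_that("classification bands follow the signed percentile", {
  set.seed(406)
  mp <- build_meta_profile(c(rnorm(300, 4, 0.5), rnorm(300, 10, 0.5)), "bi")
  top <- classify(mp, mp$max)
  expect_equal(top$call, "HIGH")
  expect_equal(top$band, "VERY_HIGH")
  mid <- classify(mp, mp$threshold)
  expect_equal(mid$call, "HIGH")      # percentile 0 counts as high
  expect_equal(mid$band, "HIGH")
  bottom <- classify(mp, mp$min)
  expect_equal(bottom$call, "LOW")
  expect_equal(bottom$band, "VERY_LOW")
  # class sign always agrees with percentile sign
  q <- runif(200, mp$min, mp$max)
  cl <- classify(mp, q)
  expect_true(all((cl$call == "HIGH") == (cl$percentile >= 0)))
  expect_error(classify(mp, 5, band_cut = 150), "band_cut")
})

test_that("histograms conserve counts over equal-width bins", {
  mp <- build_meta_profile(c(1, 1, 1, 5, 5, 5), "toy",
                           min_side_fraction = 0.1)
  h <- profile_histogram(mp, 2)
  expect_equal(h$counts, c(3, 3))
  flat <- profile_histogram(build_meta_profile(rep(3, 9), "flat"), 1)
  expect_equal(sum(flat$counts), 9)
  set.seed(407)
  mp2 <- build_meta_profile(rnorm(321, 6), "r")
  for (nb in c(1, 7, 30)) {
    expect_equal(sum(profile_histogram(mp2, nb)$counts), 321)
  }
})

test_that("well-separated bimodal rows recover threshold and component", {
  set.seed(408)
  n <- 400
  for (i in 1:10) {
    state <- runif(n) < 0.5
    v <- rnorm(n, ifelse(state, 10, 4), 0.5)
    mp <- build_meta_profile(v, "bi")
    expect_gt(mp$threshold, 4)
    expect_lt(mp$threshold, 10)
    agree <- mean((v >= mp$threshold) == state)
    expect_gte(agree, 0.99)
  }
})
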
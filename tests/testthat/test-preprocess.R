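test_that("quality filter applies strict SQI and inclusive temperature bounds", {
  s <- grid_series(6, sqi = c(0.9, 0.91, 1, 0.89, 1, 1),
                   skin_temp = c(35, 35, 32.9, 33, 42, 42.1))
  f <- filter_uniparametric(s)
  expect_equal(is.na(f$hr), c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(is.na(f$hrv), is.na(f$hr))
  expect_equal(is.na(f$rr), is.na(f$hr))
  expect_equal(is.na(f$skin_temp), c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_identical(f$activity, s$activity)          # never SQI-filtered
  # retained values unaltered; only removals
  expect_identical(f$hr[!is.na(f$hr)], s$hr[!is.na(f$hr)])
  expect_true(all(colSums(!is.na(f[2:7])) <= colSums(!is.na(s[2:7]))))
})

test_that("filter is a pass-through on clean data", {
  s <- grid_series(100, sqi = 1, skin_temp = 35)
  expect_identical(as.data.frame(filter_uniparametric(s)), as.data.frame(s))
})

test_that("baseline z-scoring matches a hand-computed mean/SD oracle", {
  base_vals <- rep(c(58, 60, 62), 30)           # 90 baseline minutes
  dose <- UTC0 + 90 * 60
  s <- grid_series(91, hr = c(base_vals, 64))
  z <- zscore_baseline(s, dose, channels = "hr")
  m <- mean(base_vals); sd_ <- sd(base_vals)
  expect_equal(z$hr[91], (64 - m) / sd_)
  expect_equal(z$hr[2], 0)                      # value at baseline mean
  expect_equal(unname(attr(z, "baseline_mean")["hr"]), m)
  expect_equal(unname(attr(z, "baseline_sd")["hr"]), sd_)
})

test_that("constant or sparse baselines invalidate a channel without error", {
  dose <- UTC0 + 90 * 60
  s <- grid_series(91, hr = 60)                 # constant channel
  expect_warning(z <- zscore_baseline(s, dose, channels = "hr"), "baseline")
  expect_true(all(is.na(z$hr)))
  s2 <- grid_series(91)
  expect_warning(z2 <- zscore_baseline(s2[c(1:30, 91), ], dose,
                                       channels = "hr"), "baseline")
  expect_true(all(is.na(z2$hr)))
})

test_that("re-z-scoring an already z-scored baseline yields mean 0, SD 1", {
  set.seed(4)
  dose <- UTC0 + 48 * 3600
  s <- grid_series(48 * 60 + 100, hr = rnorm(48 * 60 + 100, 70, 5))
  z1 <- zscore_baseline(s, dose, channels = "hr")
  z2 <- zscore_baseline(z1, dose, channels = "hr")
  in_base <- z2$time < dose
  expect_equal(mean(z2$hr[in_base]), 0, tolerance = 1e-9)
  expect_equal(sd(z2$hr[in_base]), 1, tolerance = 1e-9)
})

test_that("3-hour aggregation equals a brute-force group-by oracle", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(100:900, 1)
    anchor <- UTC0 + sample(0:5000, 1) * 60
    s <- grid_series(n, hr = rnorm(n), skin_temp = rnorm(n, 35))
    s$hr[sample(n, n %/% 5)] <- NA              # missing minutes
    agg <- aggregate_3h(s, c(UTC0, UTC0 + n * 60), anchor, channels = "hr")
    # oracle: explicit per-bin subset and mean
    ks <- sort(unique(floor(as.numeric(difftime(s$time, anchor, "UTC",
                                                units = "hours")) / 3)))
    for (k in ks) {
      lo <- anchor + k * 3 * 3600; hi <- lo + 3 * 3600
      vals <- s$hr[s$time >= lo & s$time < hi & !is.na(s$hr)]
      got <- agg$z_mean[agg$bin_start == lo]
      if (length(vals) == 0) expect_length(got, 0)
      else expect_equal(got, mean(vals), tolerance = 1e-12)
    }
  }
})

test_that("trivial aggregates: zeros stay zero, {1,3} averages to 2", {
  s <- grid_series(360, hr = 0)
  agg <- aggregate_3h(s, c(UTC0, UTC0 + 360 * 60), UTC0, channels = "hr")
  expect_true(all(agg$z_mean == 0))
  s2 <- grid_series(2, hr = c(1, 3))
  agg2 <- aggregate_3h(s2, c(UTC0, UTC0 + 7200), UTC0, channels = "hr")
  expect_equal(agg2$z_mean, 2)
})

test_that("bins are anchored at the dose so pre/post never straddle it", {
  dose <- UTC0 + 200 * 60                       # not on a 3-h boundary
  s <- grid_series(800)
  agg <- aggregate_3h(s, c(UTC0, UTC0 + 800 * 60), dose, channels = "hr")
  offs <- as.numeric(difftime(agg$bin_start, dose, units = "hours"))
  expect_true(all(offs %% 3 == 0))
})

test_that("uni-parametric detection flags |z| >= 1 in the post-dose window only", {
  dose <- UTC0
  mk <- function(z_temp, z_hr = 0) {
    structure(data.frame(
      channel = rep(c("skin_temp", "hr"), each = 4),
      bin_start = rep(dose + 3 * 3600 * (0:3), 2),
      z_mean = c(z_temp, rep(z_hr, 4)), n = 180L),
      class = c("threehour_aggregates", "data.frame"))
  }
  expect_false(any(detect_uniparam_change(mk(rep(0.99, 4)), dose,
                                          channels = c("skin_temp", "hr"))))
  fl <- detect_uniparam_change(mk(c(0, 1.4, 0, 0)), dose,
                               channels = c("skin_temp", "hr"))
  expect_true(fl[["skin_temp"]]); expect_false(fl[["hr"]])
  fl2 <- detect_uniparam_change(mk(c(0, -1.0, 0, 0)), dose,
                                channels = c("skin_temp", "hr"))
  expect_true(fl2[["skin_temp"]])               # two-sided, inclusive
  expect_error(detect_uniparam_change(mk(rep(2, 4)), dose + 13 * 3600,
                                      channels = "skin_temp"),
               class = "validation_error")
})

test_that("cohort-level flag counting is forced by construction (28 of 85)", {
  dose <- UTC0
  with_effect <- sample(rep(c(TRUE, FALSE), c(28, 57)))
  flags <- vapply(seq_len(85), function(i) {
    z <- runif(8, -0.6, 0.6)                    # null bins stay below 1 SD
    if (with_effect[i]) z[4] <- 1.5 * sample(c(-1, 1), 1)
    agg <- structure(data.frame(channel = "skin_temp",
                                bin_start = dose + 3 * 3600 * (0:7),
                                z_mean = z, n = 180L),
                     class = c("threehour_aggregates", "data.frame"))
    detect_uniparam_change(agg, dose, channels = "skin_temp")[["skin_temp"]]
  }, logical(1))
  expect_equal(sum(flags), 28L)
  expect_equal(round(100 * sum(flags) / 85), 33)
})
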
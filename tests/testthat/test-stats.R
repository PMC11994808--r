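test_that("confusion metrics reconstruct the printed study performance", {
  pe <- confusion_metrics(tpr = 1.0, spc = 0.677, n_pos = 66, n_neg = 76)
  expect_equal(100 * pe$acc, 82.7, tolerance = 5e-4)
  expect_equal(pe$npv, 1.0)                       # no false negatives at TPR = 1
  expect_equal(100 * pe$ppv, 72.9, tolerance = 1e-3)
  expect_equal(pe$fpr, 1 - pe$spc, tolerance = 1e-12)
  all1 <- confusion_metrics(1, 1, 10, 10)
  expect_true(all(unlist(all1[c("tpr", "spc", "ppv", "npv", "acc")]) == 1))
  expect_error(confusion_metrics(0, 1, 5, 5), class = "undefined_metric")
  expect_error(confusion_metrics(1.2, 0.5, 5, 5), class = "validation_error")
})

test_that("accuracy identity acc = (tpr n+ + spc n-)/(n+ + n-) holds over random inputs", {
  set.seed(51)
  for (i in 1:200) {
    tpr <- runif(1, 0.05, 1); spc <- runif(1, 0.05, 1)
    np <- sample(1:500, 1); nn <- sample(1:500, 1)
    pe <- confusion_metrics(tpr, spc, np, nn)
    expect_equal(pe$acc, (tpr * np + spc * nn) / (np + nn), tolerance = 1e-12)
    expect_equal(pe$fpr, 1 - spc, tolerance = 1e-12)
    expect_true(all(unlist(pe[c("tpr", "spc", "fpr", "ppv", "npv", "acc")]) >= 0 &
                    unlist(pe[c("tpr", "spc", "fpr", "ppv", "npv", "acc")]) <= 1))
  }
})

test_that("bootstrap performance is deterministic and exact on separated data", {
  dose <- UTC0
  zero_mcir <- mcir_from_vector(rep(0, 96 * 10), dose)    # 10 days of zeros
  pe <- bootstrap_performance(rep(TRUE, 20), list(zero_mcir, zero_mcir),
                              windows_per_control = 10, n_boot = 50, seed = 3)
  expect_equal(pe$tpr, 1); expect_equal(pe$fpr, 0)
  expect_equal(pe$ci95$tpr, c(1, 1)); expect_equal(pe$ci95$fpr, c(0, 0))
  expect_equal(pe$acc, 1)
  pe2 <- bootstrap_performance(rep(TRUE, 20), list(zero_mcir, zero_mcir),
                               windows_per_control = 10, n_boot = 50, seed = 3)
  expect_identical(pe, pe2)
  short <- mcir_from_vector(rep(0, 10), dose)
  expect_warning(expect_error(
    bootstrap_performance(rep(TRUE, 3), list(short), n_boot = 5, seed = 1),
    class = "validation_error"), "shorter")
})

test_that("KS statistic matches a brute-force ECDF-difference oracle (n, m <= 6)", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  # exact tail probability of D = 1 at n = m = 3: 2 / choose(6, 3)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  oracle_D <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(vapply(g, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
  }
  set.seed(52)
  for (i in 1:300) {
    a <- sample(1:10, sample(1:6, 1), replace = TRUE) + runif(1) # break ties across samples
    b <- sample(1:10, sample(1:6, 1), replace = TRUE)
    expect_equal(ks_two_sample(a, b)$D, oracle_D(a, b), tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1), class = "validation_error")
})

test_that("signed-rank statistic matches direct rank computation", {
  # uniform positive shift: the negative side carries zero rank sum
  pre <- c(1, 2, 3, 4, 5, 6); post <- pre + 2
  w <- wilcoxon_signed_rank(pre, post)
  expect_equal(w$W_neg, 0)
  expect_equal(w$W, 6 * 7 / 2)
  oracle_W <- function(pre, post) {
    d <- post - pre; d <- d[d != 0]
    sum(rank(abs(d))[d > 0])
  }
  set.seed(53)
  for (i in 1:200) {
    n <- sample(5:12, 1)
    pre <- rnorm(n); post <- pre + rnorm(n)
    w <- wilcoxon_signed_rank(pre, post)
    expect_equal(w$W, oracle_W(pre, post))
    expect_equal(w$W + w$W_neg, w$n * (w$n + 1) / 2)
    expect_true(w$p >= 0 && w$p <= 1)
  }
  expect_error(wilcoxon_signed_rank(1:5, 1:5), class = "validation_error")
  expect_error(wilcoxon_signed_rank(c(0, 0, 0, 0, 1), c(0, 0, 0, 0, 2)),
               class = "validation_error")      # single non-zero pair
})

test_that("Spearman rho matches the hand-ranked formula, including ties", {
  expect_equal(spearman(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman(1:6, -(1:6))$rho, -1)
  # hand computation: ranks (1..5) vs (2,1,4,3,5), sum d^2 = 4,
  # rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  oracle_rho <- function(x, y) cor(rank(x), rank(y))
  set.seed(54)
  for (i in 1:200) {
    n <- sample(4:6, 1)
    x <- sample(1:4, n, replace = TRUE) + rnorm(n, 0, 0.01)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(y) == 0) next
    expect_equal(spearman(x, y)$rho, oracle_rho(x, y), tolerance = 1e-12)
  }
  yy <- 1:10 + rnorm(10)
  s1 <- spearman(1:10, yy, alternative = "one_sided", direction = "greater")
  s2 <- spearman(1:10, yy)
  expect_true(s1$p <= s2$p + 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), class = "validation_error")
})

test_that("robust IRLS recovers exact lines and the OLS limit", {
  x <- 1:10; y <- 2 * x + 1
  for (wf in c("welsch", "andrews")) {
    f <- robust_fit(x, y, wf)
    expect_equal(f$slope, 2, tolerance = 1e-8)
    expect_equal(f$intercept, 1, tolerance = 1e-8)
    expect_true(all(f$final_weights >= 0 & f$final_weights <= 1))
  }
  set.seed(55)
  xn <- rnorm(30); yn <- 1.5 * xn + rnorm(30)
  ols <- coef(lm(yn ~ xn))
  f_inf <- robust_fit(xn, yn, "welsch", tune = 1e8)
  expect_equal(f_inf$intercept, unname(ols[1]), tolerance = 1e-6)
  expect_equal(f_inf$slope, unname(ols[2]), tolerance = 1e-6)
  expect_error(robust_fit(rep(1, 5), 1:5), class = "validation_error")
})

test_that("robust fit shrugs off a gross outlier that breaks OLS", {
  x <- 1:20
  y <- 2 * x + 1
  y[20] <- y[20] + 30
  ols_slope <- unname(coef(lm(y ~ x))[2])
  expect_gt(abs(ols_slope - 2), 0.2)
  for (wf in c("welsch", "andrews")) {
    f <- robust_fit(x, y, wf)
    expect_lt(abs(f$slope - 2), 0.05)
    expect_lt(f$final_weights[20], 0.05)          # outlier down-weighted
  }
})

test_that("population summaries recover injected level shifts", {
  mk <- function(id, shift = 0, seed = 1) {
    set.seed(seed)
    n <- 7 * 1440
    s <- grid_series(n, hr = rnorm(n, 70, 2), id = id)
    post <- s$time >= UTC0 + 2 * 86400 & s$time < UTC0 + 5 * 86400
    s$hr[post] <- s$hr[post] + shift
    s
  }
  dose <- UTC0 + 2 * 86400
  ids <- sprintf("A%02d", 1:8)
  coh <- lapply(seq_along(ids), function(i) mk(ids[i], shift = 2, seed = i))
  ev <- data.frame(participant_id = ids, dose_time = dose)
  su <- population_daily_summary(coh, ev, channels = "hr", n_days = 5)
  d1 <- su[su$day == 1, ]
  expect_equal(d1$median_delta, 2, tolerance = 0.15)
  expect_lt(d1$p, 0.05)
  d5 <- su[su$day == 5, ]                         # shift ends at day 3
  expect_lt(abs(d5$median_delta), 0.5)
  coh0 <- lapply(seq_along(ids), function(i) mk(ids[i], shift = 0, seed = i))
  su0 <- population_daily_summary(coh0, ev, channels = "hr", n_days = 2)
  expect_true(all(su0$p > 0.01))
  expect_error(population_daily_summary(coh[1], ev), class = "validation_error")
})
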
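#' Confusion-matrix metrics from rates and class sizes
#'
#' Reconstructs the full confusion matrix from a sensitivity (TPR), a
#' specificity (SPC) and the two class sizes, and derives the predictive
#' values and accuracy:
#' `TP = tpr * n_pos`, `TN = spc * n_neg`, `ppv = TP / (TP + FP)`,
#' `npv = TN / (TN + FN)`, `acc = (TP + TN) / (n_pos + n_neg)`.
#'
#' @param tpr,spc True-positive rate and specificity, fractions in [0, 1].
#' @param n_pos,n_neg Positive and negative class sizes (> 0).
#' @return A `performance_estimate` with point values
#'   `tpr, spc, fpr, ppv, npv, acc`.
#' @export
confusion_metrics <- function(tpr, spc, n_pos, n_neg) {
  if (n_pos <= 0 || n_neg <= 0)
    mcir_abort("n_pos and n_neg must be > 0", "validation_error")
  if (tpr < 0 || tpr > 1 || spc < 0 || spc > 1)
    mcir_abort("rates must be in [0, 1]", "validation_error")
  tp <- tpr * n_pos; fn <- (1 - tpr) * n_pos
  tn <- spc * n_neg; fp <- (1 - spc) * n_neg
  if (tp + fp == 0) mcir_abort("ppv undefined: no predicted positives",
                               "undefined_metric")
  if (tn + fn == 0) mcir_abort("npv undefined: no predicted negatives",
                               "undefined_metric")
  structure(list(tpr = tpr, spc = spc, fpr = 1 - spc,
                 ppv = tp / (tp + fp), npv = tn / (tn + fn),
                 acc = (tp + tn) / (n_pos + n_neg),
                 ci95 = NULL, n_boot = 0L),
            class = "performance_estimate")
}

#' @export
print.performance_estimate <- function(x, ...) {
  pct <- function(v) sprintf("%.1f%%", 100 * v)
  cat(sprintf("<performance_estimate> TPR %s, SPC %s, FPR %s, PPV %s, NPV %s, ACC %s\n",
              pct(x$tpr), pct(x$spc), pct(x$fpr), pct(x$ppv), pct(x$npv),
              pct(x$acc)))
  if (!is.null(x$ci95)) {
    for (m in names(x$ci95))
      cat(sprintf("  %s 95%% CI [%s, %s]\n", m,
                  pct(x$ci95[[m]][1]), pct(x$ci95[[m]][2])))
    cat(sprintf("  (%d bootstraps)\n", x$n_boot))
  }
  invisible(x)
}

#' Bootstrap diagnostic performance of the detectable-response rule
#'
#' Study doses supply the positive ground truth (their classifier decisions
#' in `study_decisions`); control individuals who received no vaccine supply
#' the negative ground truth.  From each control MCIR series,
#' `windows_per_control` random 72-h periods are classified with
#' [detectable_response()].  In each bootstrap replicate one window decision
#' is drawn per control individual and the study decisions are resampled
#' with replacement; confusion metrics are computed per replicate.  Point
#' estimates are the replicate means, intervals the 2.5/97.5 percentiles.
#'
#' @param study_decisions Logical vector: detectable-response decision per
#'   study dose (positives).
#' @param control_mcir List of `mcir_series`, one per control individual,
#'   each spanning well over 72 h.
#' @param windows_per_control Random 72-h windows sampled per control.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param window_h,... Passed to [detectable_response()].
#' @return A `performance_estimate` with `ci95` per metric, plus
#'   `control_window_rate`, the directly measured fraction of positive
#'   control windows.
#' @export
bootstrap_performance <- function(study_decisions, control_mcir,
                                  windows_per_control = 100L, n_boot = 1000L,
                                  seed = 1L, window_h = 72, ...) {
  if (n_boot < 1) mcir_abort("n_boot must be >= 1", "validation_error")
  with_seed(seed, {
    ctrl <- lapply(control_mcir, function(s) {
      span_h <- as.numeric(difftime(max(s$block_start), min(s$block_start),
                                    units = "hours")) + 0.25
      max_offset <- span_h - window_h
      if (max_offset < 0) {
        warning("control series shorter than the evaluation window; skipped",
                call. = FALSE)
        return(NULL)
      }
      starts <- min(s$block_start) +
        hours(stats::runif(windows_per_control, 0, max_offset))
      # snap starts onto the series' 15-min block grid
      starts <- min(s$block_start) + minutes(
        15 * floor(as.numeric(difftime(starts, min(s$block_start),
                                       units = "mins")) / 15))
      vapply(starts, function(st)
        detectable_response(s, st, window_h = window_h, ...)$detectable,
        logical(1))
    })
    ctrl <- ctrl[!vapply(ctrl, is.null, logical(1))]
    if (length(ctrl) == 0)
      mcir_abort("no usable control series", "validation_error")
    n_neg <- length(ctrl)
    n_pos <- length(study_decisions)
    mets <- c("tpr", "spc", "fpr", "ppv", "npv", "acc")
    boot <- matrix(NA_real_, n_boot, length(mets),
                   dimnames = list(NULL, mets))
    for (b in seq_len(n_boot)) {
      neg_dec <- vapply(ctrl, function(d) d[sample.int(length(d), 1L)],
                        logical(1))
      pos_dec <- study_decisions[sample.int(n_pos, n_pos, replace = TRUE)]
      tp <- sum(pos_dec); fn <- n_pos - tp
      fp <- sum(neg_dec); tn <- n_neg - fp
      boot[b, ] <- c(tp / n_pos, tn / n_neg, fp / n_neg,
                     if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                     if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                     (tp + tn) / (n_pos + n_neg))
    }
    ci <- lapply(as.data.frame(boot), function(col)
      unname(stats::quantile(col, c(0.025, 0.975), na.rm = TRUE)))
    pt <- colMeans(boot, na.rm = TRUE)
    structure(list(tpr = pt[["tpr"]], spc = pt[["spc"]], fpr = pt[["fpr"]],
                   ppv = pt[["ppv"]], npv = pt[["npv"]], acc = pt[["acc"]],
                   ci95 = ci, n_boot = as.integer(n_boot),
                   control_window_rate = mean(unlist(ctrl))),
              class = "performance_estimate")
  })
}

#' Two-sample Kolmogorov--Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the p-value from the standard
#' two-sample KS distribution (exact for small samples without ties,
#' asymptotic with the effective-n correction otherwise).
#'
#' @param a,b Numeric samples (each >= 1 value).
#' @return List `D`, `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 1 || length(b) < 1)
    mcir_abort("both samples must be non-empty", "validation_error")
  res <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped, ties get averaged ranks, and the two-sided
#' p-value uses the continuity-corrected normal approximation.  `W` is the
#' sum of ranks of the positive differences (`post - pre`); `W_neg` is the
#' negative-side sum.
#'
#' @param pre,post Paired numeric samples of equal length.
#' @param min_pairs Minimum non-zero differences required (default 5).
#' @return List `W`, `W_neg`, `n` (non-zero pairs), `p`.
#' @export
wilcoxon_signed_rank <- function(pre, post, min_pairs = 5L) {
  if (length(pre) != length(post))
    mcir_abort("pre and post must have equal length", "validation_error")
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) mcir_abort("all differences are zero", "validation_error")
  if (n < min_pairs)
    mcir_abort(sprintf("need >= %d non-zero pairs, have %d", min_pairs, n),
               "validation_error")
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  res <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  list(W = W, W_neg = n * (n + 1) / 2 - W, n = n, p = res$p.value)
}

#' Spearman rank correlation
#'
#' Tie-averaged ranks; p-value from the t-approximation.  For a one-sided
#' alternative the direction is given by `direction` (`"greater"` tests
#' rho > 0).
#'
#' @param x,y Numeric vectors (n >= 4, no missing values).
#' @param alternative `"two_sided"` or `"one_sided"`.
#' @param direction For one-sided tests: `"greater"` or `"less"`.
#' @return List `rho`, `p`, `n`.
#' @export
spearman <- function(x, y, alternative = c("two_sided", "one_sided"),
                     direction = c("greater", "less")) {
  alternative <- match.arg(alternative)
  direction <- match.arg(direction)
  if (length(x) != length(y) || length(x) < 4)
    mcir_abort("need paired samples with n >= 4", "validation_error")
  if (anyNA(x) || anyNA(y))
    mcir_abort("missing values not allowed", "validation_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    mcir_abort("correlation undefined for constant input", "validation_error")
  alt <- if (alternative == "two_sided") "two.sided" else direction
  res <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE, alternative = alt))
  list(rho = unname(res$estimate), p = res$p.value, n = length(x))
}

#' Robust straight-line fit by iteratively reweighted least squares
#'
#' Fits `y = intercept + slope * x` with per-point weights recomputed each
#' iteration from scaled residuals `u = r / (tune * s)`, where
#' `s = MAD / 0.6745` is the residual scale.  The Welsch weight is
#' `exp(-u^2)`; the Andrews weight is `sin(u)/u` for `|u| < pi` and 0
#' beyond (1 at `u = 0`).  The shared `tune` multiplies the MAD scale
#' directly; the conventional per-family constants are not folded in.
#'
#' @param x,y Numeric vectors (n >= 3, x not constant).
#' @param weight_function `"welsch"` or `"andrews"`.
#' @param tune Positive tuning multiplier on the residual scale
#'   (default 0.8).
#' @param tol Convergence tolerance on the coefficient change.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @return A `robust_fit` list: `slope`, `intercept`, `weight_function`,
#'   `tune`, `final_weights`, `n_iter`, `converged`.
#' @export
robust_fit <- function(x, y, weight_function = c("welsch", "andrews"),
                       tune = 0.8, tol = 1e-8, max_iter = 200L) {
  weight_function <- match.arg(weight_function)
  if (length(x) != length(y) || length(x) < 3)
    mcir_abort("need n >= 3 paired points", "validation_error")
  if (stats::sd(x) == 0)
    mcir_abort("x must not be constant", "validation_error")
  if (tune <= 0) mcir_abort("tune must be > 0", "validation_error")
  wfun <- switch(weight_function,
    welsch = function(u) exp(-u^2),
    andrews = function(u) ifelse(abs(u) < pi,
                                 ifelse(u == 0, 1, sin(u) / u), 0))
  X <- cbind(1, x)
  beta <- stats::lm.fit(X, y)$coefficients
  converged <- FALSE
  it <- 0L
  w <- rep(1, length(x))
  while (it < max_iter) {
    it <- it + 1L
    r <- y - X %*% beta
    s <- stats::median(abs(r - stats::median(r))) / 0.6745
    s <- max(s, .Machine$double.eps^0.5 * max(abs(r), 1))
    u <- as.numeric(r) / (tune * s)
    w <- wfun(u)
    if (sum(w > 0) < 2) break
    fit <- stats::lm.wfit(X, y, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(slope = unname(beta[2]), intercept = unname(beta[1]),
                 weight_function = weight_function, tune = tune,
                 final_weights = as.numeric(w), n_iter = it,
                 converged = converged),
            class = "robust_fit")
}

#' Population pre/post daily summaries with signed-rank tests
#'
#' Per individual and channel: the median of all pre-dose data and of each
#' post-dose day 1--5 (days relative to the dose), expressed as deltas from
#' the individual's pre-dose median.  Per day and channel, a Wilcoxon
#' signed-rank test of the individual deltas against zero.
#'
#' @param cohort_series List of `biosignal_series`.
#' @param dose_events Data frame `participant_id, dose_time` (one row per
#'   individual).
#' @param channels Channels to summarize.
#' @param n_days Post-dose days (default 5).
#' @return Data frame `channel, day, median_delta, p, n`.
#' @export
population_daily_summary <- function(cohort_series, dose_events,
                                     channels = TWIN_CHANNELS, n_days = 5L) {
  if (length(cohort_series) < 5)
    mcir_abort("need >= 5 individuals", "validation_error")
  ids <- vapply(cohort_series, function(s) attr(s, "participant_id"),
                character(1))
  deltas <- array(NA_real_, c(length(ids), length(channels), n_days),
                  dimnames = list(ids, channels, NULL))
  for (i in seq_along(cohort_series)) {
    s <- cohort_series[[i]]
    dt <- as_utc(dose_events$dose_time[dose_events$participant_id == ids[i]][1])
    pre <- s[s$time < dt, , drop = FALSE]
    for (ch in channels) {
      base_med <- stats::median(pre[[ch]], na.rm = TRUE)
      for (d in seq_len(n_days)) {
        day <- s$time >= dt + hours(24 * (d - 1)) & s$time < dt + hours(24 * d)
        if (any(day))
          deltas[i, ch, d] <- stats::median(s[[ch]][day], na.rm = TRUE) -
            base_med
      }
    }
  }
  out <- expand.grid(channel = channels, day = seq_len(n_days),
                     stringsAsFactors = FALSE)
  out$median_delta <- NA_real_; out$p <- NA_real_; out$n <- 0L
  for (r in seq_len(nrow(out))) {
    v <- deltas[, out$channel[r], out$day[r]]
    v <- v[is.finite(v)]
    out$n[r] <- length(v)
    if (length(v) >= 5) {
      out$median_delta[r] <- stats::median(v)
      if (any(v != 0))
        out$p[r] <- tryCatch(
          wilcoxon_signed_rank(rep(0, length(v)), v)$p,
          mcir_error = function(e) NA_real_)
      else out$p[r] <- 1
    }
  }
  out
}
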
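#' Quality filtering for uni-parametric analysis
#'
#' Cardiorespiratory channels (HR, HRV, RR) are ECG-derived and retained only
#' where the signal-quality index is strictly above 0.9.  Skin temperature is
#' retained only in the physiologic band [33, 42] degrees C (inclusive).
#' Activity is not SQI-filtered.  Filtering only removes values (sets them
#' `NA`); retained values are never altered.
#'
#' @param series A `biosignal_series`.
#' @return The series with failing values set to `NA`.
#' @export
filter_uniparametric <- function(series) {
  out <- series
  bad_sqi <- is.na(out$sqi) | out$sqi <= 0.9
  out$hr[bad_sqi] <- NA_real_
  out$hrv[bad_sqi] <- NA_real_
  out$rr[bad_sqi] <- NA_real_
  bad_temp <- is.na(out$skin_temp) | out$skin_temp < 33 | out$skin_temp > 42
  out$skin_temp[bad_temp] <- NA_real_
  out
}

#' Z-score channels against a 48-hour pre-dose baseline
#'
#' Each channel is transformed as `(x - m) / s`, where `m` and `s` are the
#' mean and SD of that channel's valid 1-minute samples in the 48 hours
#' before `dose_time`.  A channel with fewer than `min_samples` valid
#' baseline minutes, or with zero baseline SD, is marked invalid (all `NA`)
#' with a warning, not an error.
#'
#' @param series A (typically quality-filtered) `biosignal_series`.
#' @param dose_time Dose timestamp anchoring the baseline window
#'   `[dose_time - 48 h, dose_time)`.
#' @param channels Channels to transform.
#' @param min_samples Minimum valid baseline minutes per channel.
#' @return The series with channels replaced by z-scores; attributes
#'   `baseline_mean`, `baseline_sd` (named, original units) and
#'   `valid_channels`.
#' @export
zscore_baseline <- function(series, dose_time, channels = TWIN_CHANNELS,
                            min_samples = 60L) {
  dose_time <- as_utc(dose_time)
  in_base <- series$time >= dose_time - hours(48) & series$time < dose_time
  out <- series
  bm <- bs <- stats::setNames(rep(NA_real_, length(channels)), channels)
  valid <- stats::setNames(logical(length(channels)), channels)
  for (ch in channels) {
    x <- series[[ch]][in_base]
    x <- x[is.finite(x)]
    if (length(x) < min_samples || stats::sd(x) == 0) {
      warning(sprintf("channel '%s': invalid 48-h baseline (%d samples, sd %s)",
                      ch, length(x),
                      if (length(x) >= 2) format(stats::sd(x)) else "NA"),
              call. = FALSE)
      out[[ch]] <- NA_real_
      next
    }
    bm[ch] <- mean(x)
    bs[ch] <- stats::sd(x)
    valid[ch] <- TRUE
    out[[ch]] <- (series[[ch]] - bm[ch]) / bs[ch]
  }
  attr(out, "baseline_mean") <- bm
  attr(out, "baseline_sd") <- bs
  attr(out, "valid_channels") <- valid
  out
}

#' Aggregate z-scored minutes into contiguous 3-hour bins
#'
#' Bin edges sit at `anchor + 3k` hours, so pre- and post-dose bins never
#' straddle the dose when anchored at the dose time.  The bin summary is the
#' arithmetic mean of valid z-scored 1-minute values; bins with no valid
#' samples are absent for that channel.
#'
#' @param series A z-scored `biosignal_series` (see [zscore_baseline()]).
#' @param window Length-2 vector `[start, end]` delimiting the aggregation
#'   span (half-open).
#' @param anchor Timestamp anchoring the bin grid (usually the dose time).
#' @param channels Channels to aggregate.
#' @return A `threehour_aggregates` data frame with columns
#'   `channel, bin_start, z_mean, n`.
#' @export
aggregate_3h <- function(series, window, anchor, channels = TWIN_CHANNELS) {
  anchor <- as_utc(anchor)
  window <- as_utc(window)
  if (length(window) != 2L || window[2] <= window[1])
    mcir_abort("window must be a non-empty [start, end]", "validation_error")
  keep <- series$time >= window[1] & series$time < window[2]
  sub <- series[keep, , drop = FALSE]
  bin_idx <- floor(as.numeric(difftime(sub$time, anchor, units = "hours")) / 3)
  rows <- lapply(channels, function(ch) {
    x <- sub[[ch]]
    ok <- is.finite(x)
    if (!any(ok)) return(NULL)
    agg <- tapply(x[ok], bin_idx[ok], mean)
    cnt <- tapply(x[ok], bin_idx[ok], length)
    k <- as.numeric(names(agg))
    data.frame(channel = ch,
               bin_start = anchor + hours(3 * k),
               z_mean = as.numeric(agg),
               n = as.integer(cnt))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(channel = character(), bin_start = as_utc(character()),
                      z_mean = numeric(), n = integer())
  structure(out[order(out$channel, out$bin_start), , drop = FALSE],
            class = c("threehour_aggregates", "data.frame"),
            row.names = NULL)
}

#' Flag channels with a >= 1 SD post-dose excursion
#'
#' A channel is flagged when any 3-hour aggregate in the post-dose scan
#' window has `|z_mean| >= 1` (two-sided, inclusive threshold).
#'
#' @param aggregates A `threehour_aggregates` table.
#' @param dose_time Dose timestamp.
#' @param post_window_h Length of the post-dose scan window, hours.
#' @param channels Channels to report.
#' @return Named logical vector, one flag per channel.
#' @export
detect_uniparam_change <- function(aggregates, dose_time, post_window_h = 96,
                                   channels = TWIN_CHANNELS) {
  dose_time <- as_utc(dose_time)
  post <- aggregates$bin_start >= dose_time &
    aggregates$bin_start < dose_time + hours(post_window_h)
  if (!any(post))
    mcir_abort("no post-dose bins in aggregates", "validation_error")
  sub <- aggregates[post, , drop = FALSE]
  vapply(channels, function(ch) {
    z <- sub$z_mean[sub$channel == ch]
    length(z) > 0 && any(abs(z) >= 1)
  }, logical(1))
}
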
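# Shared fixtures, all built in code.

UTC0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")

# A noiseless, rhythm-free profile: every generated channel is constant.
flat_profile <- function(seed = 1L, ...) {
  individual_profile(hr_circadian_amp = 0, activity_day_rate = 0,
                     sqi_dropout_prob = 0, rng_seed = seed, ...)
}

flat_series <- function(days = 7, seed = 1L, ...) {
  simulate_individual(flat_profile(seed, ...), days,
                      noise_scale = 0, wear_gap_frac = 0)
}

# Hand-built biosignal series on a complete 1-minute grid.
grid_series <- function(n_min, hr = 70, hrv = 0.05, rr = 14, activity = 0.01,
                        skin_temp = 35, sqi = 1, start = UTC0, id = "T01") {
  df <- data.frame(time = start + 60 * (seq_len(n_min) - 1L),
                   hr = rep_len(hr, n_min), hrv = rep_len(hrv, n_min),
                   rr = rep_len(rr, n_min),
                   activity = rep_len(activity, n_min),
                   skin_temp = rep_len(skin_temp, n_min),
                   sqi = rep_len(sqi, n_min))
  structure(df, participant_id = id,
            class = c("biosignal_series", "data.frame"))
}

# MCIR series from a plain vector of block values anchored at `dose`.
mcir_from_vector <- function(v, dose) {
  structure(data.frame(block_start = as.POSIXct(dose, tz = "UTC") +
                         900 * (seq_along(v) - 1L),
                       mcir = v,
                       n_valid = ifelse(is.na(v), 0L, 15L)),
            class = c("mcir_series", "data.frame"))
}

# A hand-built twin model in z-units (identity normalization).
manual_twin <- function(exemplars, bandwidth = 1) {
  colnames(exemplars) <- c("hr", "hrv", "rr", "activity", "skin_temp")
  structure(list(exemplars = exemplars,
                 channel_means = setNames(rep(0, 5), colnames(exemplars)),
                 channel_sds = setNames(rep(1, 5), colnames(exemplars)),
                 bandwidth = bandwidth,
                 training_span = c(UTC0, UTC0 + 86400),
                 n_training = nrow(exemplars)),
            class = "twin_model")
}

twin_samples <- function(X, start = UTC0) {
  df <- data.frame(time = start + 60 * (seq_len(nrow(X)) - 1L), X)
  names(df) <- c("time", "hr", "hrv", "rr", "activity", "skin_temp")
  df
}
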
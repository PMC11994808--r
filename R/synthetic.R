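#' Individual physiology profile for the synthetic generator
#'
#' Describes one simulated wearer: resting means for each channel, the
#' amplitude of the 24-h heart-rate rhythm, the daytime activity-bout rate,
#' and the probability of low-signal-quality (SQI) episodes.  The generator
#' derives the skin-temperature circadian amplitude from the heart-rate
#' amplitude so that a profile with `hr_circadian_amp = 0` is rhythm-free on
#' every channel.
#'
#' @param participant_id Opaque identifier string.
#' @param hr_mean Resting heart rate, bpm (40--120).
#' @param hr_circadian_amp Amplitude of the 24-h HR sinusoid, bpm.
#' @param hrv_mean Mean heart-rate variability, seconds (> 0).
#' @param rr_mean Mean respiration rate, breaths/min (8--35).
#' @param skin_temp_mean Mean skin temperature, degrees C (33--38).
#' @param activity_day_rate Daytime activity-bout rate, bouts/hour (>= 0).
#' @param sqi_dropout_prob Stationary fraction of minutes in low-SQI
#'   episodes (0--1).
#' @param rng_seed Integer seed making the individual fully reproducible.
#' @return An object of class `individual_profile`.
#' @export
individual_profile <- function(participant_id = "P001",
                               hr_mean = 72,
                               hr_circadian_amp = 3,
                               hrv_mean = 0.05,
                               rr_mean = 14,
                               skin_temp_mean = 35,
                               activity_day_rate = 1.5,
                               sqi_dropout_prob = 0.05,
                               rng_seed = 1L) {
  p <- list(participant_id = as.character(participant_id),
            hr_mean = hr_mean, hr_circadian_amp = hr_circadian_amp,
            hrv_mean = hrv_mean, rr_mean = rr_mean,
            skin_temp_mean = skin_temp_mean,
            activity_day_rate = activity_day_rate,
            sqi_dropout_prob = sqi_dropout_prob,
            rng_seed = as.integer(rng_seed))
  validate_profile(p)
  structure(p, class = "individual_profile")
}

validate_profile <- function(p) {
  chk <- function(ok, field, rule) {
    if (!isTRUE(ok))
      mcir_abort(sprintf("invalid profile field '%s': %s", field, rule),
                 "validation_error")
  }
  chk(is.character(p$participant_id) && nzchar(p$participant_id),
      "participant_id", "non-empty string")
  chk(p$hr_mean >= 40 && p$hr_mean <= 120, "hr_mean", "must be in [40, 120] bpm")
  chk(p$hr_circadian_amp >= 0, "hr_circadian_amp", "must be >= 0")
  chk(p$hrv_mean > 0, "hrv_mean", "must be > 0 seconds")
  chk(p$rr_mean >= 8 && p$rr_mean <= 35, "rr_mean", "must be in [8, 35]")
  chk(p$skin_temp_mean >= 33 && p$skin_temp_mean <= 38, "skin_temp_mean",
      "must be in [33, 38] C")
  chk(p$activity_day_rate >= 0, "activity_day_rate", "must be >= 0")
  chk(p$sqi_dropout_prob >= 0 && p$sqi_dropout_prob <= 1, "sqi_dropout_prob",
      "must be in [0, 1]")
  invisible(p)
}

#' Post-dose response shape parameters
#'
#' The injected perturbation is additive per channel:
#' `magnitude_scale * delta * g(t)`, where `g` is a piecewise-linear ramp
#' rising from 0 at `onset_h` hours post-dose to 1 at `peak_h` and falling
#' back to 0 at `onset_h + duration_h`.  The default deltas emulate a
#' febrile inflammatory response: elevated heart rate, respiration and skin
#' temperature with suppressed heart-rate variability, lasting about three
#' days.
#'
#' @param onset_h,peak_h,duration_h Response timing, hours post-dose;
#'   requires `0 <= onset_h < peak_h < onset_h + duration_h`.
#' @param delta_hr,delta_hrv,delta_rr,delta_temp,delta_activity Peak
#'   per-channel shifts at `magnitude_scale = 1` (bpm, s, breaths/min,
#'   degrees C, g).
#' @param magnitude_scale Unitless response magnitude (0 = null response).
#' @return An object of class `response_params`.
#' @export
response_params <- function(onset_h = 4, peak_h = 20, duration_h = 64,
                            delta_hr = 4, delta_hrv = -0.012, delta_rr = 2,
                            delta_temp = 0.5, delta_activity = 0,
                            magnitude_scale = 1) {
  if (!(onset_h >= 0 && onset_h < peak_h && peak_h < onset_h + duration_h))
    mcir_abort("require 0 <= onset_h < peak_h < onset_h + duration_h",
               "validation_error")
  if (duration_h <= 0) mcir_abort("duration_h must be > 0", "validation_error")
  if (magnitude_scale < 0)
    mcir_abort("magnitude_scale must be >= 0", "validation_error")
  structure(list(onset_h = onset_h, peak_h = peak_h, duration_h = duration_h,
                 delta = c(hr = delta_hr, hrv = delta_hrv, rr = delta_rr,
                           activity = delta_activity, skin_temp = delta_temp),
                 magnitude_scale = magnitude_scale),
            class = "response_params")
}

# AR(1) noise with stationary SD `sd` and persistence `phi`.
ar1_noise <- function(n, sd, phi = 0.9) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# Alternating-state episode indicator: per-minute entry probability chosen so
# the stationary occupied fraction is `frac`; episode length geometric with
# mean `mean_len` minutes.
episode_indicator <- function(n, frac, mean_len) {
  if (frac <= 0 || n == 0L) return(logical(n))
  p_exit <- 1 / mean_len
  p_enter <- min(1, frac * p_exit / max(1e-12, 1 - frac))
  state <- logical(n)
  u <- stats::runif(n)
  s <- FALSE
  for (i in seq_len(n)) {
    s <- if (s) u[i] >= p_exit else u[i] < p_enter
    state[i] <- s
  }
  state
}

#' Simulate one individual's multichannel biosignal stream
#'
#' Generates a 1-minute-cadence record of heart rate, heart-rate variability,
#' respiration rate, activity, skin temperature and ECG signal quality (SQI)
#' for `duration_days` days.  Heart rate and skin temperature carry 24-h
#' sinusoidal rhythms (HR peaking late afternoon); activity occurs as daytime
#' bouts that drive HR and respiration upward and HRV downward; all channels
#' carry AR(1) noise (persistence 0.9) so that multi-hour baselines have
#' realistic autocorrelation.  Low-SQI episodes occur at the profile's
#' dropout rate, and short non-wear gaps remove rows from the 1-minute grid.
#'
#' @param profile An [individual_profile()].
#' @param duration_days Positive integer number of days.
#' @param start Series start time (POSIXct or string, UTC).
#' @param noise_scale Multiplier on all stochastic noise SDs (0 gives a
#'   deterministic series at the profile means).
#' @param wear_gap_frac Expected fraction of minutes removed as contiguous
#'   non-wear gaps.
#' @return A `biosignal_series`: data frame with columns
#'   `time, hr, hrv, rr, activity, skin_temp, sqi` and attribute
#'   `participant_id`.
#' @export
simulate_individual <- function(profile, duration_days,
                                start = "2021-03-01 00:00:00",
                                noise_scale = 1,
                                wear_gap_frac = 0.01) {
  validate_profile(profile)
  if (!is.numeric(duration_days) || length(duration_days) != 1L ||
      duration_days < 1 || duration_days != round(duration_days))
    mcir_abort("duration_days must be a positive integer", "validation_error")

  n <- as.integer(duration_days) * 1440L
  t0 <- as_utc(start)
  with_seed(profile$rng_seed, {
    time <- t0 + minutes(seq_len(n) - 1L)
    hour <- ((seq_len(n) - 1L) / 60) %% 24

    # Activity: daytime (08-22 h) bouts; rest level well below the 0.05 g
    # low-motion threshold used by the twin filters.
    activity <- rep(0.015, n)
    daytime <- hour >= 8 & hour < 22
    if (profile$activity_day_rate > 0 && noise_scale > 0) {
      starts <- which(daytime & stats::runif(n) < profile$activity_day_rate / 60)
      for (s in starts) {
        len <- 1L + stats::rgeom(1L, 1 / 8)          # mean ~8 min bouts
        amp <- stats::runif(1L, 0.1, 0.6)
        idx <- s:min(n, s + len - 1L)
        activity[idx] <- pmax(activity[idx], amp)
      }
      activity <- activity +
        noise_scale * abs(stats::rnorm(n, 0, 0.004))
    }

    circ_hr <- profile$hr_circadian_amp * sin(2 * pi * (hour - 10) / 24)
    # Temperature rhythm scaled off the HR amplitude (0.25 C at the default
    # 3-bpm HR amplitude) so a rhythm-free profile is flat on every channel.
    circ_temp <- (0.25 / 3) * profile$hr_circadian_amp *
      sin(2 * pi * (hour - 14) / 24)

    hr <- profile$hr_mean + circ_hr + 45 * (activity - 0.015) +
      ar1_noise(n, 2.5 * noise_scale)
    hrv <- profile$hrv_mean - 0.0008 * (hr - profile$hr_mean) +
      ar1_noise(n, 0.008 * noise_scale)
    rr <- profile$rr_mean + 10 * (activity - 0.015) +
      ar1_noise(n, 1.0 * noise_scale)
    skin_temp <- profile$skin_temp_mean + circ_temp +
      ar1_noise(n, 0.15 * noise_scale)

    sqi <- pmin(1, pmax(0, 0.97 + stats::rnorm(n, 0, 0.02 * noise_scale)))
    drop_ep <- episode_indicator(n, profile$sqi_dropout_prob, 20)
    sqi[drop_ep] <- stats::runif(sum(drop_ep), 0.3, 0.88)

    df <- data.frame(time = time,
                     hr = pmin(220, pmax(30, hr)),
                     hrv = pmax(0.005, hrv),
                     rr = pmin(45, pmax(4, rr)),
                     activity = activity,
                     skin_temp = pmin(42, pmax(30, skin_temp)),
                     sqi = sqi)

    if (wear_gap_frac > 0 && noise_scale > 0) {
      gaps <- episode_indicator(n, wear_gap_frac, 30)
      df <- df[!gaps, , drop = FALSE]
    }
    as_biosignal_series(df, profile$participant_id)
  })
}

as_biosignal_series <- function(df, participant_id) {
  rownames(df) <- NULL
  structure(df, participant_id = as.character(participant_id),
            class = c("biosignal_series", "data.frame"))
}

#' @export
print.biosignal_series <- function(x, ...) {
  cat(sprintf("<biosignal_series> participant %s: %d records, %s -- %s\n",
              attr(x, "participant_id"), nrow(x),
              format(min(x$time)), format(max(x$time))))
  invisible(x)
}

# Piecewise-linear response envelope: 0 at onset, 1 at peak, 0 at offset.
response_envelope <- function(t_h, params) {
  on <- params$onset_h; pk <- params$peak_h
  off <- params$onset_h + params$duration_h
  g <- numeric(length(t_h))
  up <- t_h >= on & t_h <= pk
  dn <- t_h > pk & t_h <= off
  g[up] <- (t_h[up] - on) / (pk - on)
  g[dn] <- (off - t_h[dn]) / (off - pk)
  g
}

#' Inject a vaccine-response perturbation into a biosignal series
#'
#' Adds `magnitude_scale * delta * g(t)` to each channel, where `g(t)` is the
#' piecewise-linear onset/peak/offset envelope of `params`.  Samples before
#' the onset are untouched.
#'
#' @param series A `biosignal_series`.
#' @param dose_time Dose timestamp, within the series span.
#' @param params A [response_params()].
#' @return A list with elements `series` (perturbed `biosignal_series`) and
#'   `truth` (ground-truth record with `true_magnitude = magnitude_scale`).
#' @export
inject_vaccine_response <- function(series, dose_time, params) {
  dose_time <- as_utc(dose_time)
  if (dose_time < min(series$time) || dose_time > max(series$time))
    mcir_abort("dose_time outside series span", "range_error")
  t_h <- as.numeric(difftime(series$time, dose_time, units = "hours"))
  g <- params$magnitude_scale * response_envelope(t_h, params)
  out <- series
  out$hr        <- pmin(220, pmax(30, out$hr + params$delta[["hr"]] * g))
  out$hrv       <- pmax(0.005, out$hrv + params$delta[["hrv"]] * g)
  out$rr        <- pmin(45, pmax(4, out$rr + params$delta[["rr"]] * g))
  out$activity  <- pmax(0, out$activity + params$delta[["activity"]] * g)
  out$skin_temp <- pmin(42, pmax(30, out$skin_temp +
                                   params$delta[["skin_temp"]] * g))
  truth <- list(participant_id = attr(series, "participant_id"),
                dose_time = dose_time,
                true_magnitude = params$magnitude_scale,
                systemic_symptom_label = NA,
                immunogenicity_value = NA_real_)
  list(series = out, truth = truth)
}

#' Simulate a cohort with heterogeneous vaccine responses
#'
#' Draws `n` individual profiles, simulates each wearer, and injects one
#' post-dose response per individual with magnitude drawn from
#' `magnitude_sampler`.  Systemic-symptom labels are Bernoulli with a
#' logistic link in the true magnitude whose intercept gives a ~20% positive
#' rate at magnitude 0 (a nocebo floor); immunogenicity values follow a
#' log-linear monotone link in magnitude with lognormal noise, so the rank
#' correlation between magnitude and titer is recoverable.
#'
#' @param n Number of individuals (>= 1).
#' @param dose_day Day of dose administration (noon), days after series
#'   start; preceded by `dose_day` full baseline days.
#' @param duration_days Total days simulated per individual.
#' @param magnitude_sampler Function of `n` returning response magnitudes.
#' @param dose_number,vaccine_label Dose metadata recorded per individual.
#' @param seed Master seed; every individual seed derives from it.
#' @param response Template [response_params()] (its `magnitude_scale` is
#'   overridden per individual).
#' @return List with `series` (list of `biosignal_series`), `truth`
#'   (data frame of ground-truth records), `doses` (dose-event table) and
#'   `profiles` (the drawn [individual_profile()]s).
#' @export
simulate_cohort <- function(n, dose_day = 5, duration_days = 9,
                            magnitude_sampler = function(k) stats::runif(k, 0, 3),
                            dose_number = 2L, vaccine_label = "synthetic-mRNA",
                            seed = 1L,
                            response = response_params()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    mcir_abort("n must be >= 1", "validation_error")
  n <- as.integer(n)
  seeds <- derive_seeds(seed, n + 1L)
  magnitudes <- with_seed(seeds[n + 1L], magnitude_sampler(n))

  series <- vector("list", n)
  truth <- vector("list", n)
  doses <- vector("list", n)
  profiles <- vector("list", n)
  start <- as_utc("2021-03-01 00:00:00")
  dose_time <- start + hours(dose_day * 24 + 12)

  for (i in seq_len(n)) {
    prof <- with_seed(seeds[i], individual_profile(
      participant_id = sprintf("S%03d", i),
      hr_mean = min(95, max(50, stats::rnorm(1, 72, 8))),
      hr_circadian_amp = stats::runif(1, 2, 4),
      hrv_mean = stats::runif(1, 0.03, 0.08),
      rr_mean = min(20, max(10, stats::rnorm(1, 14, 1.5))),
      skin_temp_mean = stats::runif(1, 34, 36.5),
      activity_day_rate = stats::runif(1, 1, 2.5),
      sqi_dropout_prob = stats::runif(1, 0.02, 0.10),
      rng_seed = seeds[i]))
    sim <- simulate_individual(prof, duration_days)
    pars <- response
    pars$magnitude_scale <- magnitudes[i]
    inj <- inject_vaccine_response(sim, dose_time, pars)
    lab <- with_seed(seeds[i] + 7L, list(
      symptom = stats::runif(1) <
        stats::plogis(stats::qlogis(0.2) + 1.2 * magnitudes[i]),
      immuno = exp(log(100) + 0.9 * magnitudes[i] + stats::rnorm(1, 0, 0.5))))
    tr <- inj$truth
    tr$systemic_symptom_label <- lab$symptom
    tr$immunogenicity_value <- lab$immuno
    series[[i]] <- inj$series
    profiles[[i]] <- prof
    truth[[i]] <- as.data.frame(tr)
    doses[[i]] <- data.frame(participant_id = prof$participant_id,
                             dose_time = dose_time,
                             dose_number = as.integer(dose_number),
                             vaccine_label = vaccine_label)
  }
  list(series = series,
       truth = do.call(rbind, truth),
       doses = do.call(rbind, doses),
       profiles = profiles)
}
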
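#' Filter samples for digital-twin training or scoring
#'
#' Both modes keep only low-motion, good-quality, complete records:
#' activity strictly below 0.05 g, skin temperature in [30, 40] degrees C and
#' SQI >= 0.9.  Training mode additionally requires heart rate in
#' [40, 250] bpm and respiration rate in [8, 35] breaths/min.  Records with
#' any missing modeled channel are dropped.
#'
#' @param series A `biosignal_series`.
#' @param mode `"training"` or `"scoring"`.
#' @return Data frame `time` plus the five modeled channels, complete rows
#'   only.
#' @export
filter_for_twin <- function(series, mode = c("training", "scoring")) {
  mode <- match.arg(mode)
  df <- as.data.frame(series)[, c("time", TWIN_CHANNELS, "sqi")]
  ok <- stats::complete.cases(df[, TWIN_CHANNELS]) & is.finite(df$sqi) &
    df$activity < 0.05 &
    df$skin_temp >= 30 & df$skin_temp <= 40 &
    df$sqi >= 0.9
  if (mode == "training")
    ok <- ok & df$hr >= 40 & df$hr <= 250 & df$rr >= 8 & df$rr <= 35
  out <- df[ok, c("time", TWIN_CHANNELS), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select exemplar vectors for the twin's memory matrix
#'
#' Guarantees coverage of the observed envelope: for each channel the
#' samples attaining that channel's minimum and maximum are always included
#' (at most 10 vectors).  The remaining slots are filled by rank-ordered
#' uniform subsampling of the training vectors sorted by Euclidean norm, so
#' selection is deterministic given the input order.
#'
#' @param X Numeric matrix of training samples (rows) by channels (columns),
#'   usually in z-units.
#' @param m Number of exemplars to keep (2 <= m <= nrow(X)).
#' @return An `m x ncol(X)` exemplar matrix.
#' @export
select_exemplars <- function(X, m) {
  n <- nrow(X)
  if (m > n) mcir_abort("m exceeds number of training samples", "validation_error")
  if (m < 2) mcir_abort("m must be >= 2", "validation_error")
  if (m == n) return(X)
  extremes <- unique(as.integer(c(apply(X, 2, which.min),
                                  apply(X, 2, which.max))))
  rest <- setdiff(seq_len(n), extremes)
  k <- m - length(extremes)
  if (k > 0) {
    ord <- rest[order(sqrt(rowSums(X[rest, , drop = FALSE]^2)))]
    pick <- ord[unique(round(seq(1, length(ord), length.out = k)))]
    # rounding can collapse adjacent ranks; backfill to hit m exactly
    short <- k - length(pick)
    if (short > 0) pick <- c(pick, setdiff(ord, pick)[seq_len(short)])
    sel <- c(extremes, pick)
  } else {
    sel <- extremes[seq_len(m)]
  }
  X[sort(sel), , drop = FALSE]
}

#' Train a personalized similarity-based baseline model
#'
#' The twin is an auto-associative kernel regression over an exemplar memory:
#' channels are z-scored by the training mean/SD, `m` exemplars are selected
#' with [select_exemplars()], and the kernel bandwidth is set to the median
#' pairwise exemplar distance (self-tuning).  Training requires at least
#' `min_samples` filtered 1-minute samples distributed over at least
#' `min_days` distinct calendar days, each such day contributing at least
#' 10% of the samples.
#'
#' @param series A `biosignal_series` of pre-dose (baseline) data; training
#'   filters are applied internally.
#' @param m Exemplar count (default 250).
#' @param min_samples Minimum filtered training samples (default 2500).
#' @param min_days Minimum distinct calendar days (default 3).
#' @return A `twin_model` with the exemplar matrix (z-units), channel
#'   means/SDs (native units), bandwidth and training metadata.
#' @export
train_twin <- function(series, m = 250L, min_samples = 2500L, min_days = 3L) {
  tr <- filter_for_twin(series, "training")
  n <- nrow(tr)
  if (n < min_samples)
    mcir_abort(sprintf(
      "insufficient baseline: %d filtered samples, %d required", n, min_samples),
      "insufficient_baseline")
  day_counts <- table(format(tr$time, "%Y-%m-%d", tz = "UTC"))
  if (sum(day_counts >= 0.10 * n) < min_days)
    mcir_abort(sprintf(
      "insufficient baseline: samples must span >= %d calendar days each holding >= 10%% of data",
      min_days), "insufficient_baseline")
  X <- as.matrix(tr[, TWIN_CHANNELS])
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  if (any(sd_ == 0))
    mcir_abort(sprintf("degenerate baseline: constant channel(s) %s",
                       paste(TWIN_CHANNELS[sd_ == 0], collapse = ", ")),
               "degenerate_baseline")
  Z <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  D <- select_exemplars(Z, min(m, n))
  h <- stats::median(stats::dist(D))
  structure(list(exemplars = D, channel_means = mu, channel_sds = sd_,
                 bandwidth = h,
                 training_span = range(tr$time),
                 n_training = n),
            class = "twin_model")
}

#' @export
print.twin_model <- function(x, ...) {
  cat(sprintf("<twin_model> %d exemplars, bandwidth %.3f, %d training samples (%s -- %s)\n",
              nrow(x$exemplars), x$bandwidth, x$n_training,
              format(x$training_span[1]), format(x$training_span[2])))
  invisible(x)
}

#' Twin estimates and residuals for new samples
#'
#' Each query is z-scored with the model's channel statistics; similarity
#' weights `w_i = k(||x - D_i||)` with the inverse-distance kernel
#' `k(d) = 1 / (1 + d/h)` are normalized to sum to one, the estimate is the
#' weighted exemplar average, and the residual is `x - xhat` in z-units.
#' Estimates therefore always lie in the exemplar convex hull.
#'
#' @param model A `twin_model`.
#' @param samples Data frame of scoring-filtered samples
#'   (see [filter_for_twin()]): `time` plus the five modeled channels.
#' @return A `residual_series` data frame: `time` and residual columns
#'   `r_hr, r_hrv, r_rr, r_activity, r_skin_temp` (z-units).
#' @export
estimate_and_residual <- function(model, samples) {
  X <- as.matrix(samples[, TWIN_CHANNELS])
  Z <- sweep(sweep(X, 2, model$channel_means), 2, model$channel_sds, "/")
  D <- model$exemplars
  # squared distances via the expansion ||z||^2 - 2 z.D' + ||D||^2
  d2 <- outer(rowSums(Z^2), rep(1, nrow(D))) - 2 * Z %*% t(D) +
    outer(rep(1, nrow(Z)), rowSums(D^2))
  d <- sqrt(pmax(d2, 0))
  W <- 1 / (1 + d / model$bandwidth)
  W <- W / rowSums(W)
  R <- Z - W %*% D
  out <- data.frame(time = samples$time, R)
  names(out) <- c("time", paste0("r_", TWIN_CHANNELS))
  structure(out, class = c("residual_series", "data.frame"))
}

#' Serialize a twin model to JSON
#'
#' Full-precision lossless round trip: `twin_from_json(twin_to_json(m))`
#' scores identically to `m`.
#'
#' @param model A `twin_model`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
twin_to_json <- function(model, path = NULL) {
  # doubles encoded as "%.17g" strings: 17 significant digits guarantee an
  # exact IEEE-754 round trip, which plain JSON number emission does not
  g17 <- function(x) sprintf("%.17g", x)
  E <- matrix(g17(model$exemplars), nrow = nrow(model$exemplars))
  obj <- list(exemplars = E,
              channel_means = as.list(g17(model$channel_means)),
              channel_sds = as.list(g17(model$channel_sds)),
              bandwidth = g17(model$bandwidth),
              training_span = format(model$training_span,
                                     "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
              n_training = model$n_training)
  names(obj$channel_means) <- names(obj$channel_sds) <- TWIN_CHANNELS
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Load a twin model from JSON
#'
#' @param x A JSON string or file path produced by [twin_to_json()].
#' @return A `twin_model`.
#' @export
twin_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  D <- matrix(as.numeric(obj$exemplars), nrow = nrow(obj$exemplars))
  colnames(D) <- TWIN_CHANNELS
  num <- function(v) stats::setNames(as.numeric(unlist(v)[TWIN_CHANNELS]),
                                     TWIN_CHANNELS)
  structure(list(exemplars = D,
                 channel_means = num(obj$channel_means),
                 channel_sds = num(obj$channel_sds),
                 bandwidth = as.numeric(obj$bandwidth),
                 training_span = as.POSIXct(obj$training_span,
                                            format = "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC"),
                 n_training = obj$n_training),
            class = "twin_model")
}
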
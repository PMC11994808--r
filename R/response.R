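# Align an MCIR series to the 288-block grid of the fixed 72-h post-dose
# window.  Missing (absent or NA) blocks count as 0 for the area and the
# window criterion — missing data can never create a response.
mcir_window_vector <- function(mcir, dose_time, window_h = 72,
                               block_minutes = 15L) {
  dose_time <- as_utc(dose_time)
  n_blocks <- as.integer(window_h * 60 / block_minutes)
  idx <- as.integer(round(as.numeric(
    difftime(mcir$block_start, dose_time, units = "mins")) / block_minutes))
  keep <- idx >= 0L & idx < n_blocks
  if (!any(keep & !is.na(mcir$mcir)))
    mcir_abort("MCIR grid covers no block in the post-dose window",
               "validation_error")
  v <- numeric(n_blocks)
  present <- logical(n_blocks)
  vals <- mcir$mcir[keep]
  at <- idx[keep] + 1L
  ok <- !is.na(vals)
  v[at[ok]] <- vals[ok]
  present[at[ok]] <- TRUE
  list(v = v, present = present, n_blocks = n_blocks)
}

#' AUC Total Response over the fixed 72-hour post-dose window
#'
#' The response area `A_i` is the sum over the window's 15-minute blocks of
#' `mcir x 15 min` (missing blocks contribute 0); the reference area `A_T`
#' is the full rectangle `window_h x 1`.  The Total Response `A_i / A_T` is
#' therefore a fraction in [0, 1].
#'
#' @param mcir An `mcir_series`.
#' @param dose_time Dose timestamp (start of the window).
#' @param window_h Window length, hours (default 72).
#' @return Scalar fraction in [0, 1].
#' @export
total_response <- function(mcir, dose_time, window_h = 72) {
  w <- mcir_window_vector(mcir, dose_time, window_h)
  sum(w$v) / w$n_blocks
}

#' Detectable-response classification
#'
#' A dose response is detectable when (a) some 6-hour sliding window (24
#' blocks, stepped one block at a time) inside the 72-h post-dose window has
#' at least 50% of its 15-minute steps with `mcir > 0.10`, and (b) the
#' window contains a persistent non-zero trend: at least `persistence_blocks`
#' consecutive blocks with `mcir > 0` (default 5 blocks, i.e. strictly more
#' than one hour).
#'
#' @param mcir An `mcir_series`.
#' @param dose_time Dose timestamp.
#' @param window_h Post-dose window, hours (default 72).
#' @param slide_window_h Sliding-window length, hours (default 6).
#' @param frac Required fraction of above-threshold blocks (default 0.5).
#' @param threshold MCIR threshold (strict `>`, default 0.10).
#' @param persistence_blocks Consecutive non-zero blocks required (default 5).
#' @return List: `detectable` (logical), `qualifying_windows` (data frame of
#'   window start/end block indices, 1-based, and start times),
#'   `n_blocks_valid`.
#' @export
detectable_response <- function(mcir, dose_time, window_h = 72,
                                slide_window_h = 6, frac = 0.5,
                                threshold = 0.10, persistence_blocks = 5L) {
  w <- mcir_window_vector(mcir, dose_time, window_h)
  v <- w$v
  win <- as.integer(slide_window_h * 4)
  need <- ceiling(frac * win)
  above <- as.numeric(v > threshold)
  n_win <- w$n_blocks - win + 1L
  counts <- if (n_win >= 1)
    cumsum(above)[win:w$n_blocks] -
      c(0, cumsum(above))[1:n_win]
  else integer(0)
  qual <- which(counts >= need)

  r <- rle(v > 0)
  persistent <- any(r$lengths[r$values] >= persistence_blocks)

  detectable <- length(qual) > 0 && persistent
  qw <- data.frame(start_block = qual, end_block = qual + win - 1L)
  qw$start_time <- as_utc(dose_time) + minutes((qw$start_block - 1L) * 15)
  list(detectable = detectable, qualifying_windows = qw,
       n_blocks_valid = sum(w$present))
}

#' Onset and offset of a detectable response
#'
#' Onset is the start of the first above-threshold block inside the earliest
#' qualifying window; offset is the end of the last above-threshold block
#' inside the latest qualifying window.
#'
#' @inheritParams detectable_response
#' @param threshold MCIR threshold (strict `>`, default 0.10).
#' @return List `onset`, `offset` (POSIXct).
#' @export
onset_offset <- function(mcir, dose_time, window_h = 72, slide_window_h = 6,
                         frac = 0.5, threshold = 0.10,
                         persistence_blocks = 5L) {
  det <- detectable_response(mcir, dose_time, window_h, slide_window_h, frac,
                             threshold, persistence_blocks)
  if (!det$detectable)
    mcir_abort("onset/offset undefined: response not detectable",
               "validation_error")
  w <- mcir_window_vector(mcir, dose_time, window_h)
  v <- w$v
  qw <- det$qualifying_windows
  first_w <- qw[which.min(qw$start_block), ]
  last_w <- qw[which.max(qw$start_block), ]
  on_block <- first_w$start_block - 1L +
    which(v[first_w$start_block:first_w$end_block] > threshold)[1]
  off_cand <- which(v[last_w$start_block:last_w$end_block] > threshold)
  off_block <- last_w$start_block - 1L + off_cand[length(off_cand)]
  dose_time <- as_utc(dose_time)
  list(onset = dose_time + minutes((on_block - 1L) * 15),
       offset = dose_time + minutes(off_block * 15))
}

#' Per-dose response summary
#'
#' Combines [total_response()], [detectable_response()] and [onset_offset()]
#' into one record.
#'
#' @inheritParams detectable_response
#' @param participant_id,dose_number Metadata carried through.
#' @return A `response_summary` list.
#' @export
response_summary <- function(mcir, dose_time, participant_id = NA_character_,
                             dose_number = NA_integer_, window_h = 72,
                             slide_window_h = 6, frac = 0.5, threshold = 0.10,
                             persistence_blocks = 5L) {
  det <- detectable_response(mcir, dose_time, window_h, slide_window_h, frac,
                             threshold, persistence_blocks)
  oo <- if (det$detectable)
    onset_offset(mcir, dose_time, window_h, slide_window_h, frac, threshold,
                 persistence_blocks)
  else list(onset = NULL, offset = NULL)
  structure(list(participant_id = participant_id,
                 dose_number = dose_number,
                 auc_total = total_response(mcir, dose_time, window_h),
                 detectable = det$detectable,
                 onset = oo$onset, offset = oo$offset,
                 n_blocks_valid = det$n_blocks_valid),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("<response_summary> %s dose %s: AUC Total Response %.4f, detectable %s\n",
              x$participant_id, x$dose_number, x$auc_total, x$detectable))
  if (x$detectable)
    cat(sprintf("  onset %s, offset %s\n", format(x$onset), format(x$offset)))
  invisible(x)
}
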
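#' Group residual minutes into 15-minute blocks
#'
#' Blocks sit on a fixed grid anchored at `anchor` (usually the dose time),
#' covering both pre- and post-dose data.  The block statistic is the mean
#' residual vector over valid minutes; blocks with fewer than
#' `min_valid_minutes` valid minutes are marked missing (`NA` means,
#' `n_valid` kept for audit).
#'
#' @param residuals A `residual_series` (see [estimate_and_residual()]).
#' @param anchor Timestamp anchoring the block grid.
#' @param block_minutes Block length, minutes (default 15).
#' @param min_valid_minutes Minimum valid minutes per block (default 3).
#' @return Data frame `block_start`, mean residual columns `r_*`, `n_valid`.
#' @export
block_residuals <- function(residuals, anchor, block_minutes = 15L,
                            min_valid_minutes = 3L) {
  anchor <- as_utc(anchor)
  rcols <- paste0("r_", TWIN_CHANNELS)
  idx <- floor(as.numeric(difftime(residuals$time, anchor, units = "mins")) /
                 block_minutes)
  ok <- stats::complete.cases(residuals[, rcols])
  sub <- residuals[ok, , drop = FALSE]
  idx <- idx[ok]
  if (nrow(sub) == 0)
    return(data.frame(block_start = as_utc(character()),
                      matrix(numeric(), 0, 5,
                             dimnames = list(NULL, rcols)),
                      n_valid = integer()))
  means <- do.call(cbind, lapply(rcols, function(cl)
    as.numeric(tapply(sub[[cl]], idx, mean))))
  colnames(means) <- rcols
  cnt <- tapply(idx, idx, length)
  n_valid <- as.integer(cnt)
  k <- as.numeric(names(cnt))
  means[n_valid < min_valid_minutes, ] <- NA_real_
  out <- data.frame(block_start = anchor + minutes(k * block_minutes), means,
                    n_valid = n_valid)
  rownames(out) <- NULL
  out[order(out$block_start), , drop = FALSE]
}

#' Calibrate the null distribution of the block statistic
#'
#' Estimates the baseline mean vector and covariance of 15-minute block-mean
#' residuals (ridge-regularized: `eps * I` with
#' `eps = 1e-6 * trace(Sigma)/5`), then stores the sorted Mahalanobis
#' distances of the baseline blocks as the empirical null for the index's
#' probability-integral transform.
#'
#' @param blocks Baseline block table from [block_residuals()].
#' @param q Zero quantile of the index (default 0.95): the expected
#'   fraction of non-zero index values under the null is `1 - q`.
#' @param min_blocks Minimum valid baseline blocks (default 50).
#' @return A `null_calibration` object.
#' @export
calibrate_null <- function(blocks, q = 0.95, min_blocks = 50L) {
  if (!(q > 0.5 && q < 1))
    mcir_abort("q must be in (0.5, 1)", "validation_error")
  rcols <- paste0("r_", TWIN_CHANNELS)
  M <- as.matrix(blocks[, rcols])
  M <- M[stats::complete.cases(M), , drop = FALSE]
  if (nrow(M) < min_blocks)
    mcir_abort(sprintf("need >= %d valid baseline blocks, have %d",
                       min_blocks, nrow(M)), "calibration_error")
  mu <- colMeans(M)
  S <- stats::cov(M)
  eps <- 1e-6 * sum(diag(S)) / 5
  if (eps == 0) eps <- 1e-12      # fully degenerate baseline
  S <- S + diag(eps, 5)
  d <- sqrt(unname(stats::mahalanobis(M, mu, S)))
  structure(list(block_stat_null = sort(d), residual_mean = mu,
                 residual_cov = S, zero_quantile = q),
            class = "null_calibration")
}

#' Compute the Multivariate Change Index of Reactogenicity
#'
#' Per 15-minute block, the Mahalanobis distance `d` of the block-mean
#' residual vector from the null calibration is passed through the empirical
#' CDF of the baseline distances and zero-floored:
#' `mcir = max(0, (F(d) - q) / (1 - q))`.  The index is in [0, 1], exactly
#' zero for typical baseline-like blocks, and saturates at 1 when `d`
#' exceeds every baseline value.  Missing blocks stay missing.
#'
#' @param blocks Block table from [block_residuals()].
#' @param calibration A `null_calibration`.
#' @return An `mcir_series` data frame: `block_start, mcir, n_valid`.
#' @export
compute_mcir <- function(blocks, calibration) {
  rcols <- paste0("r_", TWIN_CHANNELS)
  M <- as.matrix(blocks[, rcols])
  ok <- stats::complete.cases(M)
  mcirv <- rep(NA_real_, nrow(blocks))
  if (any(ok)) {
    d <- sqrt(stats::mahalanobis(M[ok, , drop = FALSE],
                                 calibration$residual_mean,
                                 calibration$residual_cov))
    Fd <- stats::ecdf(calibration$block_stat_null)(d)
    q <- calibration$zero_quantile
    mcirv[ok] <- pmax(0, (Fd - q) / (1 - q))
  }
  structure(data.frame(block_start = blocks$block_start, mcir = mcirv,
                       n_valid = blocks$n_valid),
            class = c("mcir_series", "data.frame"))
}

#' Write / read an MCIR series as CSV
#'
#' @param x An `mcir_series`.
#' @param path File path.
#' @export
write_mcir_csv <- function(x, path) {
  out <- data.frame(block_start = format(x$block_start,
                                         "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    mcir = x$mcir)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' @rdname write_mcir_csv
#' @export
read_mcir_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(data.frame(block_start = as.POSIXct(df$block_start,
                                                format = "%Y-%m-%dT%H:%M:%SZ",
                                                tz = "UTC"),
                       mcir = as.numeric(df$mcir),
                       n_valid = NA_integer_),
            class = c("mcir_series", "data.frame"))
}
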
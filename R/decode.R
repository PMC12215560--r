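#' Movement trace from tracked x/y coordinates
#'
#' Movement is the sum of the absolute frame-to-frame derivatives of the x
#' and y snout coordinates, low-pass filtered at 1 Hz with a zero-phase
#' (forward-backward) 2nd-order Butterworth filter. The first sample is
#' duplicated so the output has the input length; tiny filter undershoots
#' are clipped at zero.
#'
#' @param x,y pixel coordinate series at `rate` Hz.
#' @param rate frame rate in Hz (default 20).
#' @param cutoff low-pass cutoff in Hz (default 1).
#' @return nonnegative movement trace, same length as `x`.
#' @export
movement_from_xy <- function(x, y, rate = 20, cutoff = 1) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  m <- abs(diff(x)) + abs(diff(y))
  m <- c(m[1], m)
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  pmax(0, as.numeric(signal::filtfilt(bf, m)))
}

#' Infer nonnegative firing rates from a dF/F0 trace
#'
#' Simple nonnegative deconvolution against an AR(1) indicator kernel with
#' decay constant `decay_tau`, after removing a slowly varying baseline
#' (rolling low-percentile, smoothed). Re-convolving the output with the
#' AR(1) kernel plus the baseline reconstructs the input up to the noise
#' floor on synthetic data. The backend is pluggable: any function mapping
#' a dF/F0 trace to a nonnegative rate series can stand in.
#'
#' @param dff_trace dF/F0 series.
#' @param rate sampling rate in Hz.
#' @param decay_tau indicator decay constant in seconds (default 1.8,
#'   GCaMP6s-like).
#' @param baseline_window rolling-baseline window in seconds.
#' @return nonnegative inferred-rate series (a.u.), same length.
#' @export
infer_rates <- function(dff_trace, rate, decay_tau = 1.8,
                        baseline_window = 30) {
  stopifnot(all(is.finite(dff_trace)))
  bl <- rolling_min_med(dff_trace, rate, baseline_window, 8)$min
  bl <- ema(bl, 2, rate)
  r <- dff_trace - bl
  g <- exp(-1 / (rate * decay_tau))
  s <- pmax(0, r - g * c(r[1], head(r, -1)))
  s[1] <- max(0, r[1] - g * r[1])
  s
}

#' Time-shifted feature matrix for single-neuron decoding
#'
#' Eleven columns of the inferred-rate trace shifted from -250 ms to
#' +250 ms in 50-ms steps (at 20 Hz one bin is one sample), centered on
#' zero shift (column 6 is the unshifted trace). Shifts that fall outside
#' the trace are padded with the boundary value.
#'
#' @param rates inferred-rate series resampled to `1/bin_s` Hz.
#' @param bin_s time bin in seconds (default 0.05).
#' @param max_shift_s maximum shift in seconds (default 0.25).
#' @return matrix with one row per time bin and one column per shift,
#'   column names `shift_<ms>`.
#' @export
build_features <- function(rates, bin_s = 0.05, max_shift_s = 0.25) {
  n <- length(rates)
  k <- round(max_shift_s / bin_s)
  if (n < 2 * k) stop("trace shorter than twice the maximum shift")
  shifts <- -k:k
  X <- vapply(shifts, function(s) {
    rates[pmin(pmax(seq_len(n) + s, 1L), n)]
  }, numeric(n))
  colnames(X) <- paste0("shift_", shifts * bin_s * 1000)
  X
}

#' Decode movement from one neuron's time-shifted rate features
#'
#' Random-forest regression (128 trees, minimum terminal-node size 2,
#' variables per split `max(1, floor(p/3))`) with 5-fold cross-validation
#' on contiguous temporal blocks: each fold trains on 80% of the bins and
#' predicts the held-out 20%; predictions are concatenated. The prediction
#' power (PP) is the Pearson correlation between observed and predicted
#' movement over all bins; per-fold PPs are also reported.
#'
#' @param features matrix from [build_features()].
#' @param movement observed movement trace, one value per feature row.
#' @param n_folds number of cross-validation folds (default 5).
#' @param num_trees,min_node_size forest size and node size.
#' @param seed integer seed for the forest randomness.
#' @return an object of class `decoding_result`: list with `pp`,
#'   `pp_per_fold`, `predicted` and `fold` assignments.
#' @export
decode_movement <- function(features, movement, n_folds = 5,
                            num_trees = 128, min_node_size = 2, seed = 1L) {
  stopifnot(nrow(features) == length(movement), nrow(features) >= 500)
  if (sd(movement) == 0) stop("constant movement trace: PP undefined")
  n <- length(movement)
  fold <- cut(seq_len(n), breaks = n_folds, labels = FALSE)
  mtry <- max(1L, floor(ncol(features) / 3))
  predicted <- numeric(n)
  df <- data.frame(features)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    fit <- ranger::ranger(
      x = df[!test, , drop = FALSE], y = movement[!test],
      num.trees = num_trees, min.node.size = min_node_size, mtry = mtry,
      seed = seed + f, num.threads = 1
    )
    predicted[test] <- stats::predict(
      fit, data = df[test, , drop = FALSE], num.threads = 1
    )$predictions
  }
  pp_fold <- vapply(seq_len(n_folds), function(f) {
    cor(movement[fold == f], predicted[fold == f])
  }, 0)
  structure(list(pp = cor(movement, predicted), pp_per_fold = pp_fold,
                 predicted = predicted, fold = fold),
            class = "decoding_result")
}

#' High-frequency noise power of a calcium trace
#'
#' Mean-centers the trace, keeps only the FFT components inside the noise
#' band (default 0.5-5 Hz), inverse-transforms, and returns the sum of the
#' squared magnitudes of the band-limited time series.
#'
#' @param x dF/F0 series.
#' @param rate sampling rate in Hz; must exceed twice the band's upper
#'   edge.
#' @param band two-element frequency band in Hz.
#' @return noise power (a.u.).
#' @export
noise_power <- function(x, rate, band = c(0.5, 5)) {
  n <- length(x)
  stopifnot(n >= 2 * rate / band[1], rate >= 2 * band[2])
  x0 <- x - mean(x)
  f <- (seq_len(n) - 1) * rate / n
  fmir <- pmin(f, rate - f)
  xf <- fft(x0)
  xf[fmir < band[1] | fmir > band[2]] <- 0
  xb <- fft(xf, inverse = TRUE) / n
  sum(Mod(xb)^2)
}
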
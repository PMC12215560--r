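#' Baseline noise of a voltage trace
#'
#' The baseline noise is defined from the samples lying strictly below the
#' median of the whole trace: events are depolarizing, so the lower half of
#' the amplitude distribution is event-free and its spread estimates the
#' recording noise. For pure Gaussian noise this returns the SD of the
#' lower half-distribution, about 0.60 times the true noise SD.
#'
#' @param trial a [voltage_trial()] or numeric vector of samples.
#' @return noise SD in mV; 0 (with a warning) for a constant trace.
#' @export
baseline_noise_sd <- function(trial) {
  x <- if (inherits(trial, "voltage_trial")) trial$samples else as.numeric(trial)
  stopifnot(length(x) >= 100)
  below <- x[x < median(x)]
  if (length(below) < 2L) {
    warning("constant trace: baseline noise is zero")
    return(0)
  }
  sd(below)
}

#' Detect depolarizing events in a voltage trial
#'
#' The trace is smoothed with a centered moving average of `lowpass_ms`
#' width; contiguous runs above `baseline + threshold_sd * noise_sd` lasting
#' at least `min_duration_ms` become events. The baseline is the whole-trace
#' median and the noise SD comes from [baseline_noise_sd()]. With
#' `post_stim_only = TRUE` the search starts `post_stim_gap` seconds after
#' the offset of the last stimulus, so the evoked PSP train itself is
#' excluded.
#'
#' @param trial a [voltage_trial()].
#' @param post_stim_only restrict detection to the post-stimulus window.
#' @param threshold_sd threshold in units of baseline noise SD (default 3).
#' @param lowpass_ms moving-average window in ms (default 100).
#' @param min_duration_ms minimum event duration in ms (default 10).
#' @param post_stim_gap gap (s) after the last stimulus offset before the
#'   post-stimulus window opens.
#' @param amplitude `"mean"` (default) reports the mean of the smoothed
#'   trace above baseline during the event, `"peak"` the maximum.
#' @return data frame with columns `onset`, `duration` (s) and
#'   `mean_amplitude` (mV), one row per event.
#' @export
detect_events <- function(trial, post_stim_only = TRUE, threshold_sd = 3,
                          lowpass_ms = 100, min_duration_ms = 10,
                          post_stim_gap = 0.05,
                          amplitude = c("mean", "peak")) {
  stopifnot(inherits(trial, "voltage_trial"))
  amplitude <- match.arg(amplitude)
  fs <- trial$sampling_rate
  if (fs < 1000) stop("sampling rate must be at least 1 kHz")
  x <- trial$samples
  baseline <- median(x)
  thr <- baseline + threshold_sd * baseline_noise_sd(x)
  sm <- moving_average(x, round(lowpass_ms / 1000 * fs))

  start_i <- 1L
  if (post_stim_only && length(trial$stim_times) > 0) {
    start_i <- round((max(trial$stim_times) + trial$stim_duration +
                        post_stim_gap) * fs) + 1L
    if (start_i >= length(x)) stop("empty post-stimulus window")
  }
  idx <- start_i:length(x)
  above <- sm[idx] > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_duration_ms / 1000 * fs
  if (!any(keep)) {
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      mean_amplitude = numeric(0)))
  }
  out <- lapply(which(keep), function(r) {
    i <- idx[starts[r]:ends[r]]
    amp <- if (amplitude == "mean") mean(sm[i] - baseline) else max(sm[i] - baseline)
    data.frame(onset = (i[1] - 1L) / fs,
               duration = length(i) / fs,
               mean_amplitude = amp)
  })
  do.call(rbind, out)
}

#' Classify detected events as short events or DSDPs
#'
#' A conservative 200-ms duration cut separates short events from
#' long-lasting plateau depolarizations (DSDPs).
#'
#' @param events data frame from [detect_events()].
#' @param dsdp_ms duration threshold in ms (default 200).
#' @return the events with an added `class` column, `"dsdp"` for durations
#'   strictly greater than the threshold and `"short"` otherwise.
#' @export
classify_events <- function(events, dsdp_ms = 200) {
  events$class <- ifelse(events$duration > dsdp_ms / 1000, "dsdp", "short")
  events
}

#' Trial-level DSDP statistics
#'
#' @param trials_events list of classified event data frames, one per trial
#'   (empty data frames for event-free trials).
#' @param post_window duration (s) of the post-stimulus search window per
#'   trial, used for the frequency denominators.
#' @return a list with `probability` (fraction of trials with at least one
#'   DSDP), `total_duration` (mean per-trial summed DSDP duration, s),
#'   `frequency` (DSDPs per second of post-stimulus time, Hz) and
#'   `short_event_frequency` (same for short events).
#' @export
summarize_dsdp <- function(trials_events, post_window) {
  stopifnot(length(trials_events) >= 1, post_window > 0)
  n_trials <- length(trials_events)
  per_trial <- lapply(trials_events, function(ev) {
    if (is.null(ev) || nrow(ev) == 0) {
      c(n_dsdp = 0, dur = 0, n_short = 0)
    } else {
      is_d <- ev$class == "dsdp"
      c(n_dsdp = sum(is_d), dur = sum(ev$duration[is_d]),
        n_short = sum(!is_d))
    }
  })
  m <- do.call(rbind, per_trial)
  list(
    probability = mean(m[, "n_dsdp"] > 0),
    total_duration = mean(m[, "dur"]),
    frequency = sum(m[, "n_dsdp"]) / (n_trials * post_window),
    short_event_frequency = sum(m[, "n_short"]) / (n_trials * post_window)
  )
}
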
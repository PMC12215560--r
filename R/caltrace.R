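#' Parameters of the two-channel calcium correction chain
#'
#' Defaults follow the published processing chain: 500-ms exponential
#' moving average smoothing, rolling windows of 180 s, 8th-percentile
#' minima and median centers for the channel rescaling, neuropil
#' coefficient r = 0.7, and a 30th-percentile F0 for the dF/F0
#' normalization.
#'
#' @param smoothing_window EMA window in seconds.
#' @param rolling_window rolling-statistics window in seconds (centered;
#'   truncated at the trace edges).
#' @param low_percentile percentile (0-100) for the window minima.
#' @param neuropil_r neuropil subtraction coefficient in `[0, 1]`.
#' @param f0_percentile percentile (0-100) of the whole F trace used as F0.
#' @return an object of class `correction_params`.
#' @export
correction_params <- function(smoothing_window = 0.5, rolling_window = 180,
                              low_percentile = 8, neuropil_r = 0.7,
                              f0_percentile = 30) {
  stopifnot(low_percentile > 0, low_percentile < 100,
            f0_percentile > 0, f0_percentile < 100,
            neuropil_r >= 0, neuropil_r <= 1,
            smoothing_window >= 0, rolling_window > 0)
  structure(list(smoothing_window = smoothing_window,
                 rolling_window = rolling_window,
                 low_percentile = low_percentile,
                 neuropil_r = neuropil_r,
                 f0_percentile = f0_percentile),
            class = "correction_params")
}

# exponential moving average; alpha = 2/(n+1) with n the window in samples
ema <- function(x, window_s, rate) {
  n_w <- window_s * rate
  if (n_w <= 1) return(x)
  alpha <- 2 / (n_w + 1)
  as.numeric(filter(alpha * x, 1 - alpha, method = "recursive",
                    init = x[1]))
}

# rolling low-percentile and median over centered windows, truncated at the
# edges; returns a list(min, med) of vectors aligned to x.
rolling_min_med <- function(x, rate, window_s, low_percentile) {
  n <- length(x)
  half <- round(window_s / 2 * rate)
  lo_p <- low_percentile / 100
  mn <- numeric(n)
  md <- numeric(n)
  for (t in seq_len(n)) {
    w <- x[max(1L, t - half):min(n, t + half)]
    q <- quantile(w, c(lo_p, 0.5), names = FALSE, type = 7)
    mn[t] <- q[1]
    md[t] <- q[2]
  }
  list(min = mn, med = md)
}

#' Rescale the structural channel onto the activity channel
#'
#' After smoothing both channels with a 500-ms EMA, the structural trace is
#' mapped onto the activity trace's range at every sample using rolling
#' (180-s centered window) 8th percentiles (`minR`, `minG`) and medians
#' (`medR`, `medG`):
#' `FR_rescaled(t) = (FR(t) - minR)/medR * medG + minG`.
#'
#' @param fg,fr activity- and structural-channel traces (a.u.).
#' @param rate frame rate in Hz.
#' @param params a [correction_params()].
#' @return list with `fr_rescaled`, the smoothed `fg_smooth` and the
#'   rolling `med_g` (needed by [axial_correct()]).
#' @export
rescale_structural <- function(fg, fr, rate, params = correction_params()) {
  stopifnot(length(fg) == length(fr))
  fg_s <- ema(fg, params$smoothing_window, rate)
  fr_s <- ema(fr, params$smoothing_window, rate)
  rg <- rolling_min_med(fg_s, rate, params$rolling_window,
                        params$low_percentile)
  rr <- rolling_min_med(fr_s, rate, params$rolling_window,
                        params$low_percentile)
  if (any(rr$med == 0)) stop("structural-channel rolling median is zero")
  fr_rescaled <- (fr_s - rr$min) / rr$med * rg$med + rg$min
  list(fr_rescaled = fr_rescaled, fg_smooth = fg_s, med_g = rg$med)
}

#' Axial (ratiometric) artifact correction
#'
#' Divides the activity channel by the rescaled structural channel and
#' restores the local scale with the rolling activity-channel median:
#' `FG_corrected(t) = FG(t) / FR_rescaled(t) * medG(t)`. Samples where
#' `FR_rescaled <= 0` are flagged in the `bad` mask (correction undefined
#' there; values carried through as NA).
#'
#' @inheritParams rescale_structural
#' @return list with `fg_corrected` and logical mask `bad`.
#' @export
axial_correct <- function(fg, fr, rate, params = correction_params()) {
  rs <- rescale_structural(fg, fr, rate, params)
  bad <- rs$fr_rescaled <= 0
  fg_corrected <- ifelse(bad, NA_real_,
                         rs$fg_smooth / rs$fr_rescaled * rs$med_g)
  list(fg_corrected = fg_corrected, bad = bad)
}

#' Neuropil subtraction
#'
#' `F(t) = FG_cell_corrected(t) - r * FG_neuropil_corrected(t)` with
#' r = 0.7 by default.
#'
#' @param fg_cell_corrected,fg_neuropil_corrected corrected traces.
#' @param r neuropil coefficient.
#' @return the F trace.
#' @export
neuropil_subtract <- function(fg_cell_corrected, fg_neuropil_corrected,
                              r = 0.7) {
  stopifnot(length(fg_cell_corrected) == length(fg_neuropil_corrected))
  fg_cell_corrected - r * fg_neuropil_corrected
}

#' Normalized calcium trace dF/F0
#'
#' `(F - F0)/F0` with F0 a low percentile (default 30th) of the whole F
#' trace.
#'
#' @param f the F trace.
#' @param f0_percentile percentile (0-100) defining F0.
#' @return dF/F0 trace.
#' @export
dff <- function(f, f0_percentile = 30) {
  f0 <- quantile(f, f0_percentile / 100, names = FALSE, na.rm = TRUE)
  if (!is.finite(f0) || f0 <= 0) {
    stop("nonpositive F0 baseline (", signif(f0, 4),
         "): neuropil subtraction left no positive baseline")
  }
  (f - f0) / f0
}

#' Full correction chain for one ROI
#'
#' Applies [rescale_structural()] + [axial_correct()] to the cell and (with
#' its own structural reference) the neuropil traces, then
#' [neuropil_subtract()] and [dff()].
#'
#' @param rec a [roi_recording()].
#' @param params a [correction_params()].
#' @return list with `dff`, `f`, `fg_cell_corrected`,
#'   `fg_neuropil_corrected`, and the `bad` sample mask.
#' @export
correct_roi <- function(rec, params = correction_params()) {
  stopifnot(inherits(rec, "roi_recording"))
  cell <- axial_correct(rec$fg_cell, rec$fr_cell, rec$frame_rate, params)
  np <- axial_correct(rec$fg_neuropil, rec$fr_neuropil, rec$frame_rate,
                      params)
  f <- neuropil_subtract(cell$fg_corrected, np$fg_corrected,
                         params$neuropil_r)
  list(dff = dff(f, params$f0_percentile), f = f,
       fg_cell_corrected = cell$fg_corrected,
       fg_neuropil_corrected = np$fg_corrected,
       bad = cell$bad | np$bad)
}
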
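#' @rdname simulate_calcium_recording
#' @param fg_cell,fr_cell,fg_neuropil,fr_neuropil fluorescence time series
#'   (a.u.) for the activity (GCaMP-like) and structural (mRuby-like)
#'   channels of the cell ROI and its neuropil ring.
#' @param frame_rate imaging frame rate in Hz.
#' @param depth imaging-plane depth in um (upper plane -100, lower -300).
#' @param id neuron identifier.
#' @export
roi_recording <- function(fg_cell, fr_cell, fg_neuropil, fr_neuropil,
                          frame_rate = 10, depth = -100, id = 1L) {
  n <- length(fg_cell)
  stopifnot(length(fr_cell) == n, length(fg_neuropil) == n,
            length(fr_neuropil) == n,
            all(is.finite(c(fg_cell, fr_cell, fg_neuropil, fr_neuropil))),
            frame_rate > 0)
  structure(list(fg_cell = fg_cell, fr_cell = fr_cell,
                 fg_neuropil = fg_neuropil, fr_neuropil = fr_neuropil,
                 frame_rate = frame_rate, depth = depth, id = id),
            class = "roi_recording")
}

# white noise band-limited below `cutoff` (Hz) via FFT masking, rescaled to
# unit SD (zero vector if the band is empty).
lp_noise <- function(n, rate, cutoff) {
  x <- rnorm(n)
  f <- (seq_len(n) - 1) * rate / n
  keep <- (f <= cutoff) | (rate - f <= cutoff)
  keep[1] <- FALSE
  xf <- fft(x)
  xf[!keep] <- 0
  y <- Re(fft(xf, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) rep(0, n) else y / s
}

# GCaMP6s-like indicator kernel: difference of exponentials, rise 0.2 s,
# decay 1.8 s, unit peak.
calcium_kernel <- function(rate, rise = 0.2, decay = 1.8, length_s = 10) {
  t <- seq(0, length_s, by = 1 / rate)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

convolve_spikes <- function(spikes, kernel) {
  n <- length(spikes)
  out <- numeric(n)
  idx <- which(spikes > 0)
  for (i in idx) {
    j <- i:min(i + length(kernel) - 1L, n)
    out[j] <- out[j] + spikes[i] * kernel[seq_along(j)]
  }
  out
}

#' Simulate a two-channel calcium imaging session with known ground truth
#'
#' Emulates the signal structure of dual-plane two-photon recordings with
#' an activity indicator (GCaMP6s-like) and a structural marker
#' (mRuby2-like): Poisson spiking (optionally modulated by a 20-Hz
#' behavioral movement trace through a per-neuron coupling gain),
#' kernel-convolved calcium transients, a shared slow (below 0.2 Hz)
#' log-normal multiplicative motion artifact per imaging plane, additive
#' common neuropil contamination, and white measurement noise. The
#' structural channel carries the same artifact but no activity.
#'
#' @param n_upper,n_lower neurons in the upper (-100 um) and lower
#'   (-300 um) planes.
#' @param duration recording duration in seconds.
#' @param rate mean firing rate in Hz.
#' @param artifact_amp log-SD of the multiplicative artifact (0 disables).
#' @param neuropil_gain gain of the additive neuropil contamination in the
#'   activity channel.
#' @param coupling per-neuron exponent coupling firing to the normalized
#'   movement trace (`rate * m(t)^coupling`); 0 means uncoupled. Scalar or
#'   one value per neuron.
#' @param frame_rate imaging frame rate in Hz (default 10).
#' @param noise_sd white measurement noise SD (a.u.).
#' @param seed integer seed.
#' @return list with `rois` (list of [roi_recording()]), `movement`
#'   (20-Hz behavioral trace, 1/f-like slow structure) and `truth` (list:
#'   per-neuron spike count vectors, coupling gains, per-plane artifact
#'   traces, neuropil trace).
#' @export
simulate_calcium_recording <- function(n_upper = 4, n_lower = 4,
                                       duration = 300, rate = 0.2,
                                       artifact_amp = 0.15,
                                       neuropil_gain = 0.5,
                                       coupling = 0,
                                       frame_rate = 10,
                                       noise_sd = 0.5,
                                       seed = 1L) {
  stopifnot(duration > 0, rate >= 0, artifact_amp >= 0, neuropil_gain >= 0,
            all(coupling >= 0), n_upper + n_lower >= 1)
  n_neur <- n_upper + n_lower
  coupling <- rep_len(coupling, n_neur)
  n <- round(duration * frame_rate)
  n20 <- round(duration * 20)
  kern <- calcium_kernel(frame_rate)

  with_seed(seed, {
    # behavioral trace: rectified 1/f-shaped noise, slow structure
    z <- rnorm(n20)
    f <- (seq_len(n20) - 1) * 20 / n20
    fmir <- pmin(f, 20 - f)
    shape <- 1 / pmax(fmir, 0.02)
    shape[1] <- 0
    zf <- fft(z) * shape
    slow <- Re(fft(zf, inverse = TRUE)) / n20
    movement <- pmax(0, slow / sd(slow) + 0.5)

    # movement resampled to the imaging rate, normalized to mean 1
    m_frame <- approx(seq_len(n20) / 20, movement,
                      xout = seq_len(n) / frame_rate, rule = 2)$y
    m_norm <- m_frame / mean(m_frame)

    artifact <- list(
      upper = if (artifact_amp > 0) exp(artifact_amp * lp_noise(n, frame_rate, 0.2)) else rep(1, n),
      lower = if (artifact_amp > 0) exp(artifact_amp * lp_noise(n, frame_rate, 0.2)) else rep(1, n)
    )
    neuropil <- 20 * (1 + 0.15 * lp_noise(n, frame_rate, 0.5))

    depths <- c(rep(-100, n_upper), rep(-300, n_lower))
    spikes_list <- vector("list", n_neur)
    rois <- vector("list", n_neur)
    for (i in seq_len(n_neur)) {
      lam <- rate * m_norm^coupling[i] / frame_rate
      spikes <- rpois(n, lam)
      spikes_list[[i]] <- spikes
      s_t <- if (depths[i] == -100) artifact$upper else artifact$lower
      f_true <- 50 + 40 * convolve_spikes(spikes, kern)
      fg_cell <- f_true * s_t + neuropil_gain * neuropil +
        rnorm(n, 0, noise_sd)
      fr_cell <- 80 * s_t + rnorm(n, 0, noise_sd)
      fg_np <- neuropil * s_t + rnorm(n, 0, noise_sd)
      fr_np <- 60 * s_t + rnorm(n, 0, noise_sd)
      rois[[i]] <- roi_recording(fg_cell, fr_cell, fg_np, fr_np,
                                 frame_rate, depths[i], id = i)
    }
    list(rois = rois, movement = movement,
         truth = list(spikes = spikes_list, coupling = coupling,
                      artifact = artifact, neuropil = neuropil))
  })
}
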
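#' Bimodality coefficient of a sample
#'
#' Sarle's bimodality coefficient
#' \deqn{BC = (S^2 + 1) / (K + 3 (N-1)^2 / ((N-2)(N-3)))}
#' where `S` is the sample skewness and `K` the sample excess kurtosis
#' (moment estimators, as in MATLAB's `skewness`/`kurtosis` with the latter
#' shifted by 3). For a Gaussian, BC tends to 1/3; a 50/50 two-point mixture
#' tends to 1. Values above 0.5 indicate bimodality.
#'
#' @param x numeric sample, `length(x) >= 4`.
#' @return list with `bc`, `skewness`, `kurtosis` (excess) and `n`.
#' @export
bimodality_coefficient <- function(x) {
  n <- length(x)
  if (n < 4) stop("need at least 4 samples")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero-variance sample")
  s <- mean((x - m)^3) / m2^1.5
  k <- mean((x - m)^4) / m2^2 - 3
  bc <- (s^2 + 1) / (k + 3 * ((n - 1)^2 / (n - 2)) / (n - 3))
  list(bc = bc, skewness = s, kurtosis = k, n = n)
}

# Deterministic 1-D 2-means: initial centers at the sample extremes.
kmeans_1d_2 <- function(x) {
  stats::kmeans(x, centers = matrix(c(min(x), max(x))), iter.max = 100)
}

#' Classify trials as NMDA-spike trials from evoked amplitudes
#'
#' Tests the per-trial evoked-amplitude distribution for bimodality with
#' [bimodality_coefficient()]. If BC exceeds `bc_threshold` (default 0.5)
#' the amplitudes are split by 2-means; the higher-mean cluster is labelled
#' as NMDA spikes, and the NMDA-spike strength is the fraction of NMDA
#' trials multiplied by their mean amplitude. A unimodal distribution gives
#' fraction and strength 0.
#'
#' @param trial_amplitudes numeric vector of per-trial mean evoked
#'   amplitudes (mV).
#' @param bc_threshold bimodality call threshold (default 0.5).
#' @return an object of class `bimodality_result`: list with `bc`,
#'   `skewness`, `kurtosis`, `n`, `is_bimodal`, logical `spike_labels` per
#'   trial, `nmda_fraction`, `nmda_mean_amplitude` and `nmda_strength`.
#' @export
nmda_classify <- function(trial_amplitudes, bc_threshold = 0.5) {
  b <- bimodality_coefficient(trial_amplitudes)
  res <- c(b, list(is_bimodal = b$bc > bc_threshold))
  if (res$is_bimodal) {
    km <- kmeans_1d_2(trial_amplitudes)
    hi <- which.max(km$centers)
    labels <- km$cluster == hi
    if (all(labels) || !any(labels)) {
      labels <- rep(FALSE, length(trial_amplitudes))
    }
    res$spike_labels <- labels
    res$nmda_fraction <- mean(labels)
    res$nmda_mean_amplitude <-
      if (any(labels)) mean(trial_amplitudes[labels]) else 0
  } else {
    res$spike_labels <- rep(FALSE, length(trial_amplitudes))
    res$nmda_fraction <- 0
    res$nmda_mean_amplitude <- 0
  }
  res$nmda_strength <- res$nmda_fraction * res$nmda_mean_amplitude
  class(res) <- "bimodality_result"
  res
}

#' Reversal potential from amplitude-voltage pairs
#'
#' Ordinary least-squares line of event amplitude against holding
#' potential; the reversal potential is the zero-crossing voltage.
#'
#' @param amplitudes event amplitudes (mV) at each holding potential.
#' @param holding_potentials holding potentials (mV), at least two distinct.
#' @return reversal potential in mV.
#' @export
reversal_potential <- function(amplitudes, holding_potentials) {
  stopifnot(length(amplitudes) == length(holding_potentials),
            length(unique(holding_potentials)) >= 2)
  fit <- lm(amplitudes ~ holding_potentials)
  slope <- coef(fit)[2]
  amp_scale <- sd(amplitudes) + mean(abs(amplitudes)) + 1e-12
  if (!is.finite(slope) ||
      abs(slope) < 1e-8 * amp_scale / diff(range(holding_potentials))) {
    stop("slope indistinguishable from zero: no reversal")
  }
  unname(-coef(fit)[1] / slope)
}

#' Nernst equilibrium potential for potassium
#'
#' \eqn{E_K = (RT/F)\,\ln([K]_o/[K]_i)} with R = 8.314 J mol^-1 K^-1 and
#' F = 96485 C mol^-1.
#'
#' @param k_out,k_in extracellular and intracellular K+ concentration (mM).
#' @param temperature_c temperature in degrees Celsius (default 36, the
#'   recording-bath temperature).
#' @return equilibrium potential in mV.
#' @export
nernst_potassium <- function(k_out, k_in, temperature_c = 36) {
  stopifnot(k_out > 0, k_in > 0)
  t_kelvin <- temperature_c + 273.15
  1000 * (8.314 * t_kelvin / 96485) * log(k_out / k_in)
}

#' Select down-state trials and per-trial baseline Vm
#'
#' The baseline Vm is the mean over the 5 ms preceding the first stimulus.
#' A per-trial up/down-state threshold is the 10th percentile of the
#' trial's Vm plus `threshold_offset` mV; a trial is a down-state trial when
#' its baseline lies below that threshold and below `vm_ceiling`.
#'
#' @param trials list of [voltage_trial()] with defined `stim_times`.
#' @param vm_ceiling absolute ceiling on the baseline Vm in mV (-50 or -40
#'   depending on dataset).
#' @param threshold_offset offset above the 10th percentile in mV
#'   (default 3; 1.5 for the pre-current-injection selection).
#' @return data frame with `trial`, `baseline_vm`, `threshold`, `selected`.
#' @export
downstate_trials <- function(trials, vm_ceiling = -50, threshold_offset = 3) {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    stopifnot(inherits(tr, "voltage_trial"), length(tr$stim_times) > 0)
    fs <- tr$sampling_rate
    i_stim <- round(tr$stim_times[1] * fs)
    i_lo <- i_stim - round(0.005 * fs) + 1L
    if (i_lo < 1L) stop("first stimulus earlier than 5 ms into the trace")
    baseline <- mean(tr$samples[i_lo:i_stim])
    thr <- unname(quantile(tr$samples, 0.10)) + threshold_offset
    data.frame(trial = tr$id, baseline_vm = baseline, threshold = thr,
               selected = baseline < thr & baseline < vm_ceiling)
  })
  do.call(rbind, rows)
}

#' Input resistance from a hyperpolarizing current step
#'
#' The quotient of the voltage deflection (minimum Vm during the pulse
#' minus the baseline Vm over the 5 ms before pulse onset) by the injected
#' current, reported in megaohms.
#'
#' @param trial a [voltage_trial()].
#' @param pulse_onset,pulse_duration current-step onset and duration (s).
#' @param pulse_amp_pa injected current in pA (default -20).
#' @return input resistance in megaohms.
#' @export
input_resistance <- function(trial, pulse_onset, pulse_duration,
                             pulse_amp_pa = -20) {
  stopifnot(inherits(trial, "voltage_trial"), pulse_amp_pa != 0)
  fs <- trial$sampling_rate
  n <- length(trial$samples)
  i_on <- round(pulse_onset * fs)
  i_off <- min(round((pulse_onset + pulse_duration) * fs), n)
  if (i_on < round(0.005 * fs) + 1L || i_off > n || i_on >= i_off) {
    stop("pulse window must lie inside the trace, at least 5 ms in")
  }
  baseline <- mean(trial$samples[(i_on - round(0.005 * fs) + 1L):i_on])
  v_min <- min(trial$samples[(i_on + 1L):i_off])
  # mV / pA = GOhm; report MOhm
  1000 * (v_min - baseline) / pulse_amp_pa
}
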
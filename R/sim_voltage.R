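#' Configuration for synthetic dendritic voltage trials
#'
#' Bundles every knob of the trial simulator. Defaults emulate dendritic
#' whole-cell recordings during an afferent stimulation train: five 5-ms
#' pulses at 8 Hz riding on a resting potential near -65 mV, with optional
#' NMDA-spike trials (a high-amplitude mode in the evoked-PSP amplitude
#' distribution) and delayed sustained dendritic potentials (DSDPs): plateau
#' depolarizations with variable onset after the last stimulus.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param n_trials number of trials.
#' @param trial_length trial duration in seconds.
#' @param stim_times stimulus onset times in seconds (default five pulses at
#'   8 Hz starting at 0.5 s).
#' @param stim_duration stimulus pulse width in seconds.
#' @param noise_sd Gaussian baseline noise SD in mV.
#' @param psp_amp_small,psp_amp_large peak amplitude (mV) of the ordinary-PSP
#'   and NMDA-spike amplitude modes.
#' @param p_nmda probability that a trial expresses the large (NMDA) mode.
#' @param dsdp_rate expected number of plateau events per post-stimulus
#'   window; the integer part is injected deterministically and the
#'   fractional part as a Bernoulli draw, so `dsdp_rate = 1` yields exactly
#'   one plateau per trial.
#' @param dsdp_onset_jitter uniform onset jitter (s) added after the last
#'   stimulus.
#' @param dsdp_duration_range plateau duration range in seconds,
#'   `c(min, max)`.
#' @param dsdp_amp plateau amplitude in mV.
#' @param resting_vm resting membrane potential in mV.
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#' @return an object of class `voltage_sim_config`.
#' @export
voltage_sim_config <- function(sampling_rate = 10000,
                               n_trials = 20,
                               trial_length = 3,
                               stim_times = 0.5 + (0:4) / 8,
                               stim_duration = 0.005,
                               noise_sd = 0.2,
                               psp_amp_small = 2,
                               psp_amp_large = 10,
                               p_nmda = 0,
                               dsdp_rate = 0,
                               dsdp_onset_jitter = 0.3,
                               dsdp_duration_range = c(0.25, 0.5),
                               dsdp_amp = 5,
                               resting_vm = -65,
                               seed = 1L) {
  stopifnot(
    sampling_rate > 0,
    n_trials >= 1,
    trial_length > 0,
    p_nmda >= 0, p_nmda <= 1,
    noise_sd >= 0,
    psp_amp_small >= 0, psp_amp_large >= 0, dsdp_amp >= 0,
    dsdp_rate >= 0,
    dsdp_onset_jitter >= 0,
    length(dsdp_duration_range) == 2L,
    dsdp_duration_range[1] < dsdp_duration_range[2]
  )
  if (length(stim_times) > 0 && max(stim_times) >= trial_length) {
    stop("trial_length must exceed the last stimulus time")
  }
  structure(
    list(
      sampling_rate = sampling_rate, n_trials = n_trials,
      trial_length = trial_length, stim_times = sort(stim_times),
      stim_duration = stim_duration, noise_sd = noise_sd,
      psp_amp_small = psp_amp_small, psp_amp_large = psp_amp_large,
      p_nmda = p_nmda, dsdp_rate = dsdp_rate,
      dsdp_onset_jitter = dsdp_onset_jitter,
      dsdp_duration_range = dsdp_duration_range,
      dsdp_amp = dsdp_amp, resting_vm = resting_vm, seed = seed
    ),
    class = "voltage_sim_config"
  )
}

#' Construct a voltage trial object
#'
#' @param samples membrane potential samples in mV.
#' @param sampling_rate Hz.
#' @param stim_times stimulus onsets in seconds.
#' @param stim_duration pulse width in seconds.
#' @param holding_potential optional holding potential in mV.
#' @param id trial identifier.
#' @return an object of class `voltage_trial`.
#' @export
voltage_trial <- function(samples, sampling_rate, stim_times = numeric(0),
                          stim_duration = 0.005, holding_potential = NA_real_,
                          id = 1L) {
  stopifnot(all(is.finite(samples)), sampling_rate > 0,
            !is.unsorted(stim_times))
  if (length(stim_times) > 0 &&
      max(stim_times) > length(samples) / sampling_rate) {
    stop("stimulus times must lie within the trace")
  }
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         stim_times = stim_times, stim_duration = stim_duration,
         holding_potential = holding_potential, id = id),
    class = "voltage_trial"
  )
}

# Double-exponential PSP kernel, unit peak. rise/decay in seconds.
psp_kernel <- function(sampling_rate, rise = 0.002, decay = 0.020,
                       length_s = 0.25) {
  t <- seq(0, length_s, by = 1 / sampling_rate)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

# Flat-top plateau with logistic (sigmoid) edges; `edge` is the 10-90%
# transition width in seconds.
plateau_waveform <- function(t, onset, duration, amp, edge = 0.010) {
  scale <- edge / (2 * log(9)) # logistic scale giving 10-90% width = edge
  amp / (1 + exp(-(t - onset) / scale)) / (1 + exp((t - onset - duration) / scale))
}

#' Simulate trial-structured dendritic voltage recordings
#'
#' Generates `config$n_trials` trials of resting potential plus Gaussian
#' noise, stimulus-locked double-exponential PSPs (each trial draws the
#' small or, with probability `p_nmda`, the large NMDA amplitude mode), and
#' zero or more flat-top plateau events (DSDPs) with variable onset after
#' the last stimulus. Every injected event is recorded in the ground truth.
#'
#' @param config a [voltage_sim_config()].
#' @return a list with elements `trials` (list of [voltage_trial()]) and
#'   `truth` (data frame with columns `trial`, `kind` in
#'   `psp`/`nmda`/`dsdp`, `onset`, `duration`, `amplitude`).
#' @export
simulate_voltage_trials <- function(config) {
  stopifnot(inherits(config, "voltage_sim_config"))
  fs <- config$sampling_rate
  n_samp <- round(config$trial_length * fs)
  t <- (seq_len(n_samp) - 1) / fs
  kern <- psp_kernel(fs)
  last_stim <- if (length(config$stim_times)) max(config$stim_times) else 0

  with_seed(config$seed, {
    trials <- vector("list", config$n_trials)
    truth <- list()
    for (tr in seq_len(config$n_trials)) {
      v <- config$resting_vm +
        if (config$noise_sd > 0) rnorm(n_samp, 0, config$noise_sd) else 0
      ev <- list()
      # stimulus-locked PSPs; amplitude mode chosen once per trial
      if (length(config$stim_times) > 0) {
        is_nmda <- runif(1) < config$p_nmda
        base_amp <- if (is_nmda) config$psp_amp_large else config$psp_amp_small
        for (st in config$stim_times) {
          amp <- base_amp * runif(1, 0.9, 1.1)
          i0 <- round(st * fs) + 1L
          idx <- i0:min(i0 + length(kern) - 1L, n_samp)
          v[idx] <- v[idx] + amp * kern[seq_along(idx)]
          ev[[length(ev) + 1L]] <- data.frame(
            trial = tr, kind = if (is_nmda) "nmda" else "psp",
            onset = st, duration = 0.05, amplitude = amp
          )
        }
      }
      # delayed plateau events after the last stimulus
      n_dsdp <- floor(config$dsdp_rate) +
        rbinom(1, 1, config$dsdp_rate - floor(config$dsdp_rate))
      cursor <- last_stim + config$stim_duration + 0.1
      for (k in seq_len(n_dsdp)) {
        onset <- cursor + runif(1, 0, config$dsdp_onset_jitter)
        dur <- runif(1, config$dsdp_duration_range[1],
                     config$dsdp_duration_range[2])
        if (onset + dur > config$trial_length - 0.05) {
          dur <- max(config$dsdp_duration_range[1],
                     config$trial_length - 0.05 - onset)
          if (onset + dur > config$trial_length - 0.05) break
        }
        v <- v + plateau_waveform(t, onset, dur, config$dsdp_amp)
        ev[[length(ev) + 1L]] <- data.frame(
          trial = tr, kind = "dsdp", onset = onset, duration = dur,
          amplitude = config$dsdp_amp
        )
        cursor <- onset + dur + 0.1
      }
      trials[[tr]] <- voltage_trial(v, fs, config$stim_times,
                                    config$stim_duration, id = tr)
      truth[[tr]] <- if (length(ev)) do.call(rbind, ev) else NULL
    }
    truth <- do.call(rbind, truth)
    if (is.null(truth)) {
      truth <- data.frame(trial = integer(0), kind = character(0),
                          onset = numeric(0), duration = numeric(0),
                          amplitude = numeric(0))
    }
    list(trials = trials, truth = truth)
  })
}
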
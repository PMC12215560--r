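test_that("baseline noise estimates the lower-half SD of the trace", {
  # closed-form oracle: for Gaussian noise, the SD of the samples below the
  # median is the SD of the upper-truncated (at the mean) normal:
  # sqrt(1 - (2*dnorm(0))^2/... ) = sqrt(1 - 2/pi*... ) = 0.6028 sigma
  lam <- dnorm(0) / pnorm(0)
  sd_half <- sqrt(1 - lam^2)
  set.seed(101)
  x <- rnorm(1e6, mean = -65, sd = 0.4)
  expect_equal(baseline_noise_sd(x), 0.4 * sd_half, tolerance = 0.01)

  expect_warning(r <- baseline_noise_sd(rep(-70, 200)), "constant")
  expect_equal(r, 0)

  # a large plateau occupying ~10% of the trace sits above the median and
  # barely perturbs the estimate
  y <- x
  y[1:1e5] <- y[1:1e5] + 30
  expect_lt(abs(baseline_noise_sd(y) - baseline_noise_sd(x)) /
              baseline_noise_sd(x), 0.05)
})

test_that("an injected plateau is detected once with the right duration", {
  cfg <- voltage_sim_config(n_trials = 1, noise_sd = 0.2, dsdp_rate = 1,
                            dsdp_duration_range = c(0.299, 0.301),
                            dsdp_amp = 5, seed = 41)
  sim <- simulate_voltage_trials(cfg)
  ev <- detect_events(sim$trials[[1]])
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$duration - 0.3), 0.1)
  expect_gt(ev$mean_amplitude, 0)
})

test_that("pure noise produces essentially no long events", {
  n_events <- 0
  for (s in 1:20) {
    cfg <- voltage_sim_config(n_trials = 1, noise_sd = 0.1, dsdp_rate = 0,
                              p_nmda = 0, seed = 1000 + s)
    tr <- simulate_voltage_trials(cfg)$trials[[1]]
    ev <- detect_events(tr)
    n_events <- n_events + sum(ev$duration >= 0.2)
  }
  expect_equal(n_events, 0)
})

test_that("a brief spikelet fails the duration criterion after smoothing", {
  fs <- 10000
  set.seed(43)
  v <- rnorm(3 * fs, -65, 0.2)
  i0 <- 2 * fs
  v[i0:(i0 + 0.005 * fs)] <- v[i0:(i0 + 0.005 * fs)] + 2
  tr <- voltage_trial(v, fs, stim_times = 0.5 + (0:4) / 8)
  # brute-force oracle on the smoothed trace: max never clears threshold
  sm <- l23pipe:::moving_average(v, fs * 0.1)
  thr <- median(v) + 3 * baseline_noise_sd(v)
  expect_lt(max(sm[(1.2 * fs):length(sm)]), thr)
  expect_equal(nrow(detect_events(tr)), 0)
})

test_that("detection is invariant to adding a constant to the trace", {
  cfg <- voltage_sim_config(n_trials = 1, dsdp_rate = 1, seed = 47)
  tr <- simulate_voltage_trials(cfg)$trials[[1]]
  ev1 <- detect_events(tr)
  tr2 <- tr
  tr2$samples <- tr2$samples + 12.5
  ev2 <- detect_events(tr2)
  expect_equal(ev1, ev2)
})

test_that("the 200-ms rule separates short events from DSDPs", {
  ev <- data.frame(onset = c(1, 2, 3), duration = c(0.199, 0.3, 0.2),
                   mean_amplitude = c(1, 2, 3))
  cl <- classify_events(ev)
  expect_identical(cl$class, c("short", "dsdp", "short"))
  # idempotent, duration-only
  expect_identical(classify_events(cl)$class, cl$class)
  empty <- classify_events(data.frame(onset = numeric(0),
                                      duration = numeric(0),
                                      mean_amplitude = numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("DSDP summaries count probabilities and rates correctly", {
  mk <- function(durs) {
    if (length(durs) == 0) {
      return(data.frame(onset = numeric(0), duration = numeric(0),
                        mean_amplitude = numeric(0), class = character(0)))
    }
    classify_events(data.frame(onset = seq_along(durs), duration = durs,
                               mean_amplitude = 1))
  }
  trials <- c(lapply(1:4, function(i) mk(0.3)), lapply(1:6, function(i) mk(numeric(0))))
  s <- summarize_dsdp(trials, post_window = 2)
  expect_equal(s$probability, 0.4)
  # probability equals 1 - fraction of DSDP-free trials exactly
  expect_equal(s$probability, 1 - 6 / 10)
  expect_equal(s$frequency, 4 / (10 * 2))

  # 6 DSDPs over 30 s of post-stimulus time -> 0.2 Hz
  trials2 <- lapply(1:10, function(i) if (i <= 6) mk(0.25) else mk(numeric(0)))
  expect_equal(summarize_dsdp(trials2, post_window = 3)$frequency, 0.2)

  empty <- summarize_dsdp(lapply(1:5, function(i) mk(numeric(0))), 2)
  expect_equal(unlist(empty), c(probability = 0, total_duration = 0,
                                frequency = 0, short_event_frequency = 0))
})
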
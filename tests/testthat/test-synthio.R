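test_that("voltage generator honors its contract and ground truth is complete", {
  cfg <- voltage_sim_config(n_trials = 6, noise_sd = 0.1, dsdp_rate = 0,
                            p_nmda = 0, seed = 2)
  sim <- simulate_voltage_trials(cfg)
  expect_length(sim$trials, 6)
  expect_true(all(sim$truth$kind == "psp"))
  expect_equal(sum(sim$truth$trial == 1), length(cfg$stim_times))

  cfg1 <- voltage_sim_config(n_trials = 8, dsdp_rate = 1, seed = 3)
  sim1 <- simulate_voltage_trials(cfg1)
  dsdp <- sim1$truth[sim1$truth$kind == "dsdp", ]
  expect_equal(as.vector(table(factor(dsdp$trial, levels = 1:8))), rep(1L, 8))
  expect_true(all(dsdp$duration >= 0.25 & dsdp$duration <= 0.5))
  # every event lies within its trial window
  expect_true(all(sim1$truth$onset >= 0 &
                    sim1$truth$onset + sim1$truth$duration <= cfg1$trial_length))
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- voltage_sim_config(n_trials = 3, dsdp_rate = 0.5, p_nmda = 0.4,
                            seed = 11)
  s1 <- simulate_voltage_trials(cfg)
  s2 <- simulate_voltage_trials(cfg)
  expect_identical(s1, s2)

  m1 <- simulate_morphologies(2, 2, seed = 5)
  m2 <- simulate_morphologies(2, 2, seed = 5)
  expect_identical(m1, m2)
  f1 <- tempfile(fileext = ".swc")
  f2 <- tempfile(fileext = ".swc")
  write_swc(m1$trees[[1]], f1)
  write_swc(m2$trees[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))

  c1 <- simulate_calcium_recording(1, 1, duration = 60, seed = 7)
  c2 <- simulate_calcium_recording(1, 1, duration = 60, seed = 7)
  expect_identical(c1, c2)

  expect_identical(simulate_laminar_profile("POm", seed = 4),
                   simulate_laminar_profile("POm", seed = 4))
})

test_that("generator rejects invalid configurations", {
  expect_error(voltage_sim_config(trial_length = 0.5,
                                  stim_times = c(0.2, 0.8)),
               "last stimulus")
  expect_error(voltage_sim_config(p_nmda = 1.5))
  expect_error(voltage_sim_config(dsdp_duration_range = c(0.5, 0.25)))
  expect_error(simulate_calcium_recording(1, 1, duration = 60,
                                          neuropil_gain = -1, seed = 1))
  expect_error(simulate_calcium_recording(1, 1, duration = -5, seed = 1))
})

test_that("injected plateau durations are recovered within one low-pass window", {
  cfg <- voltage_sim_config(n_trials = 10, noise_sd = 0.2, dsdp_rate = 1,
                            dsdp_amp = 5, seed = 21)
  sim <- simulate_voltage_trials(cfg)
  for (i in seq_along(sim$trials)) {
    ev <- classify_events(detect_events(sim$trials[[i]]))
    ev <- ev[ev$class == "dsdp", ]
    tru <- sim$truth[sim$truth$trial == i & sim$truth$kind == "dsdp", ]
    expect_equal(nrow(ev), nrow(tru))
    expect_lt(abs(ev$duration - tru$duration), 0.1)
  }
})

test_that("BT and ST parameter sets produce opposite apical/basal ratios", {
  bt <- simulate_morphologies(1, 0, seed = 6)
  st <- simulate_morphologies(0, 1, seed = 6)
  fb <- compute_features(bt$trees[[1]])
  fs <- compute_features(st$trees[[1]])
  expect_gt(fb$length_ratio, 1)
  expect_lt(fs$length_ratio, 1)
  expect_error(simulate_morphologies(0, 0, seed = 1))
})

test_that("calcium generator contracts: uncoupled, artifact-free and silent regimes", {
  sim <- simulate_calcium_recording(2, 0, duration = 60, coupling = c(0, 2),
                                    seed = 9)
  expect_identical(sim$truth$coupling, c(0, 2))

  flat <- simulate_calcium_recording(1, 0, duration = 60, artifact_amp = 0,
                                     noise_sd = 0.3, seed = 9)
  expect_identical(flat$truth$artifact$upper, rep(1, 600))
  # structural channel reduces to constant + white noise
  expect_lt(sd(flat$rois[[1]]$fr_cell), 3 * 0.3)

  quiet <- simulate_calcium_recording(1, 0, duration = 60, rate = 0,
                                      neuropil_gain = 0, artifact_amp = 0,
                                      noise_sd = 0.3, seed = 9)
  expect_identical(sum(quiet$truth$spikes[[1]]), 0L)
  expect_lt(abs(mean(quiet$rois[[1]]$fg_cell) - 50), 0.2)
  expect_lt(sd(quiet$rois[[1]]$fg_cell), 3 * 0.3)
})

test_that("laminar templates have the documented depth structure", {
  edges <- seq(0, 800, 25)
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  vpm <- simulate_laminar_profile("VPM", edges, seed = 2)
  expect_true(centers[which.max(vpm$values)] >= 300 &&
                centers[which.max(vpm$values)] <= 500)
  pom <- simulate_laminar_profile("POm", edges, seed = 2)
  expect_gt(pom$values[1], pom$values[which.min(abs(centers - 300))])
  for (aff in c("POm", "VPM", "M1", "S2")) {
    expect_true(all(simulate_laminar_profile(aff, edges, seed = 3)$values >= 0))
  }
  expect_error(simulate_laminar_profile("LGN", edges, seed = 1),
               "unknown afferent")
})
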
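test_that("bimodality coefficient matches an independent moment oracle", {
  skip_if_not_installed("e1071")
  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:200, 1)
    x <- switch(1 + s %% 3,
                rnorm(n),
                rexp(n),
                c(rnorm(n %/% 2), rnorm(n - n %/% 2, 5)))
    bc_oracle <- (e1071::skewness(x, type = 1)^2 + 1) /
      (e1071::kurtosis(x, type = 1) + 3 * ((n - 1)^2 / (n - 2)) / (n - 3))
    expect_equal(bimodality_coefficient(x)$bc, bc_oracle,
                 tolerance = 1e-12)
  }
})

test_that("bimodality coefficient hits its analytic limits", {
  # 50/50 two-point mass: S = 0, K = -2 exactly
  n <- 1000
  x <- rep(c(0, 1), each = n / 2)
  b <- bimodality_coefficient(x)
  expect_equal(b$skewness, 0)
  expect_equal(b$kurtosis, -2)
  expect_equal(b$bc, 1 / (-2 + 3 * ((n - 1)^2 / (n - 2)) / (n - 3)))
  expect_lt(abs(b$bc - 1), 0.01)

  set.seed(7)
  expect_lt(abs(bimodality_coefficient(rnorm(1e5))$bc - 1 / 3), 0.02)

  expect_error(bimodality_coefficient(c(1, 2, 3)), "at least 4")
  expect_error(bimodality_coefficient(rep(2, 10)), "zero-variance")
})

test_that("NMDA-spike trials are split out of a bimodal amplitude mixture", {
  set.seed(9)
  amps <- c(rnorm(15, 3, 0.5), rnorm(15, 12, 1))
  res <- nmda_classify(amps)
  expect_true(res$is_bimodal)
  expect_equal(res$nmda_fraction, 0.5, tolerance = 0.1)
  expect_equal(res$nmda_strength, 6, tolerance = 1)
  expect_identical(res$spike_labels, c(rep(FALSE, 15), rep(TRUE, 15)))

  uni <- nmda_classify(rnorm(30, 5, 0.5))
  expect_false(uni$is_bimodal)
  expect_equal(uni$nmda_fraction, 0)
  expect_equal(uni$nmda_strength, 0)
  expect_equal(uni$nmda_strength, uni$nmda_fraction * uni$nmda_mean_amplitude)
})

test_that("reversal potential comes from the OLS zero crossing", {
  # collinear points on a slope-0.1 line through -94 mV
  expect_equal(reversal_potential(c(4.4, 0.4, -2.6), c(-50, -90, -120)),
               -94, tolerance = 1e-9)
  # scale invariance of the root
  expect_equal(reversal_potential(2 * c(4.4, 0.4, -2.6), c(-50, -90, -120)),
               -94, tolerance = 1e-9)
  # two-point exact line
  expect_equal(reversal_potential(c(3, -3), c(-60, -120)), -90)
  expect_error(reversal_potential(c(1, 1, 1), c(-60, -90, -120)),
               "no reversal")
})

test_that("Nernst potential follows the closed form", {
  expect_equal(nernst_potassium(5, 5, 36), 0)
  expect_equal(nernst_potassium(5, 140, 36),
               nernst_potassium(10, 280, 36))
  # physiological pipette composition at 36 C
  expect_equal(nernst_potassium(2.5, 138, 36), -106.8484, tolerance = 1e-3)
})

test_that("down-state trials are selected by percentile threshold and ceiling", {
  fs <- 10000
  mk <- function(v, id) voltage_trial(v, fs, stim_times = 0.5, id = id)
  const <- mk(rep(-70, fs), 1)
  # bistable trace, baseline window sampled in the down state
  t <- seq_len(fs)
  bist <- rep(c(-55, -75), each = fs / 2)
  bist_tr <- mk(bist[c((fs / 2 + 1):fs, 1:(fs / 2))], 2) # down state first
  high <- mk(rep(-45, fs), 3)
  out <- downstate_trials(list(const, bist_tr, high), vm_ceiling = -50)
  expect_equal(out$baseline_vm, c(-70, -75, -45))
  expect_equal(out$threshold[1], -67)
  expect_identical(out$selected, c(TRUE, TRUE, FALSE))
  early <- voltage_trial(rep(-70, fs), fs, stim_times = 1e-4)
  expect_error(downstate_trials(list(early)), "5 ms")
})

test_that("input resistance is the deflection over the injected current", {
  fs <- 10000
  v <- rep(-70, fs)
  v[2001:4000] <- -72 # -2 mV deflection
  tr <- voltage_trial(v, fs)
  expect_equal(input_resistance(tr, 0.2, 0.2, -20), 100)
  v2 <- rep(-70, fs)
  v2[2001:4000] <- -74.4
  expect_equal(input_resistance(voltage_trial(v2, fs), 0.2, 0.2, -20), 220)
  expect_equal(input_resistance(tr, 0.5, 0.2, -20), 0)
  expect_error(input_resistance(tr, 0.2, 0.2, 0))
})
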
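# Spike detection, passive parameters, excitability, QC.

test_that("spike detection finds constructed spikes and rejects slow ones", {
  flat <- new_sweep("f", "current_clamp", 50, rep(-75, 5000), rep(0, 5000),
                    protocol_descriptor("square_family", 20, onset_ms = 10))
  expect_identical(nrow(detect_spikes(flat)), 0L)

  times <- c(200, 300, 400)
  sw <- make_spike_sweep(times, peak_dvdt = 150)
  ev <- detect_spikes(sw)
  expect_identical(nrow(ev), 3L)
  expect_true(all(abs(ev$time_ms - times) <= 0.5))
  # unfiltered peak dV/dt of the construction is its rising slope
  expect_equal(ev$peak_dvdt, rep(150, 3), tolerance = 0.05)
  # threshold voltage reported near the rise onset
  expect_true(all(ev$threshold_v > -76 & ev$threshold_v < -65))

  slow <- make_spike_sweep(times, peak_dvdt = 15)
  expect_identical(nrow(detect_spikes(slow)), 0L)
})

test_that("spike detection needs enough bandwidth", {
  sw <- make_spike_sweep(c(200), sample_khz = 5)
  expect_error(detect_spikes(sw), "too low to resolve")
})

test_that("input resistance: Ohm's law, noise, spontaneous-event exclusion", {
  ideal <- synth_rc_step_sweeps(3, r_in = 500, tau_m = 20, noise_sd_mv = 0)
  expect_equal(as.numeric(measure_input_resistance(ideal)), 500,
               tolerance = 1e-6)

  noisy <- synth_rc_step_sweeps(40, r_in = 300, tau_m = 30, noise_sd_mv = 0.2,
                                seed = 101)
  expect_equal(as.numeric(measure_input_resistance(noisy)), 300,
               tolerance = 3 / 300)

  contaminated <- synth_rc_step_sweeps(40, r_in = 300, tau_m = 30,
                                       noise_sd_mv = 0.2, seed = 102,
                                       transient_sweeps = c(3, 9, 17, 25, 33),
                                       transient_mv = 5)
  est <- measure_input_resistance(contaminated)
  expect_setequal(attr(est, "excluded"), c(3, 9, 17, 25, 33))
  expect_equal(as.numeric(est), 300, tolerance = 0.01)
})

test_that("time constant: recovery, onset/offset averaging, misfit warning", {
  sw <- synth_rc_step_sweeps(20, r_in = 300, tau_m = 30, noise_sd_mv = 0.1,
                             seed = 103)
  tau <- measure_time_constant(sw)
  expect_equal(as.numeric(tau), 30, tolerance = 0.6 / 30)
  seg <- attr(tau, "per_segment")
  expect_equal(as.numeric(tau), mean(seg))

  # biexponential membrane: single-tau compromise between 5 and 50 ms,
  # flagged, and matching an independent grid-search of the same objective
  rate <- 50
  n <- round(650 * rate)
  t <- (seq_len(n) - 1) / rate
  on <- t >= 100 & t < 500
  after <- t >= 500
  biexp <- function(tt) -2.5 * (1 - exp(-tt / 5)) - 2.5 * (1 - exp(-tt / 50))
  v <- rep(-75, n)
  v[on] <- -75 + biexp(t[on] - 100)
  # offset relaxation: each component decays back with its own constant
  toff <- t[after] - 500
  v[after] <- -75 - 2.5 * (1 - exp(-400 / 5)) * exp(-toff / 5) -
    2.5 * (1 - exp(-400 / 50)) * exp(-toff / 50)
  i <- rep(0, n); i[on] <- -10
  sw2 <- list(new_sweep("bi", "current_clamp", rate, v, i,
                        protocol_descriptor("hyperpol_step", -10,
                                            duration_ms = 400)))
  w <- testthat::capture_warnings(tau2 <- measure_time_constant(sw2))
  expect_match(w, "poorly described by a single exponential", all = FALSE)
  # independent oracle: grid search of the same least-squares objective on
  # the onset segment
  idx <- which(t >= 102 & t <= 200)
  tt <- t[idx] - 100
  vv <- v[idx]
  taus <- seq(1, 100, by = 0.05)
  sse <- vapply(taus, function(ta) {
    X <- cbind(exp(-tt / ta), 1)
    sum(.lm.fit(X, vv)$residuals^2)
  }, numeric(1))
  tau_oracle <- taus[which.min(sse)]
  expect_equal(attr(tau2, "per_segment")[["onset"]], tau_oracle,
               tolerance = 0.02)

  # non-decaying segment errors
  ramp <- rep(-75, n); ramp[on] <- -75 + (t[on] - 100) * 0.01
  sw3 <- list(new_sweep("r", "current_clamp", rate, ramp, i,
                        protocol_descriptor("hyperpol_step", -10,
                                            duration_ms = 400)))
  expect_error(suppressWarnings(measure_time_constant(sw3)))
})

test_that("RMP is the mean accepted baseline and ordering-invariant", {
  mk <- function(base) synth_rc_step_sweeps(1, r_in = 300, tau_m = 30,
                                            rmp = base, noise_sd_mv = 0)[[1]]
  expect_equal(measure_rmp(list(mk(-80))), -80, tolerance = 1e-9)
  two <- list(mk(-80), mk(-78))
  expect_equal(measure_rmp(two), -79, tolerance = 1e-9)
  expect_equal(measure_rmp(rev(two)), -79, tolerance = 1e-9)
})

test_that("passive estimates are invariant to sweep ordering", {
  sw <- synth_rc_step_sweeps(20, r_in = 300, tau_m = 30, noise_sd_mv = 0.2,
                             seed = 104)
  perm <- sample(seq_along(sw))
  expect_equal(as.numeric(measure_input_resistance(sw)),
               as.numeric(measure_input_resistance(sw[perm])))
  expect_equal(as.numeric(measure_time_constant(sw)),
               as.numeric(measure_time_constant(sw[perm])))
})

test_that("capacitance: Q over dV, RC transient, zero transient", {
  # rectangular transient of known charge: 30 pA for 5 ms = 150 fC on -5 mV
  rate <- 50
  n <- 200 * rate
  t <- (seq_len(n) - 1) / rate
  i <- rep(0, n)
  i[t >= 50 & t < 55] <- -30
  v <- rep(-70, n); v[t >= 50 & t < 150] <- -75
  sw <- new_sweep("vc", "voltage_clamp", rate, v, i,
                  protocol_descriptor("vc_step", -5, onset_ms = 50,
                                      holding = -70))
  expect_equal(measure_capacitance(sw), 30, tolerance = 0.01)

  rc <- synth_vc_cap_sweep(c_m = 25, r_s = 2, noise_sd_pa = 2, seed = 105)
  expect_equal(measure_capacitance(rc), 25, tolerance = 0.5 / 25)

  flatv <- rep(-70, n); flatv[t >= 50 & t < 150] <- -75
  flat <- new_sweep("vc0", "voltage_clamp", rate, flatv, rep(0, n),
                    protocol_descriptor("vc_step", -5, onset_ms = 50,
                                        holding = -70))
  expect_warning(cm0 <- measure_capacitance(flat), "no detectable")
  expect_identical(cm0, 0)
})

test_that("excitability: first-spike features, max rate, depolarization block", {
  fam <- make_square_family(c(0, 4, 12, 30, 55, 40))
  exc <- measure_excitability(fam)
  expect_equal(exc$max_rate, 55)
  expect_identical(exc$block_index, 6L)
  expect_equal(exc$peak_dvdt, 150, tolerance = 0.05)
  expect_true(exc$ap_threshold > -76 && exc$ap_threshold < -65)

  single <- make_square_family(c(1))
  exc1 <- measure_excitability(single)
  expect_equal(exc1$max_rate, 1)
  expect_true(is.na(exc1$block_index))

  expect_error(measure_excitability(make_square_family(c(0, 0))),
               "no spiking sweep")
})

test_that("EIF threshold detection lands near the model threshold", {
  p <- eif_params(c_m = 30, g_l = 3, e_l = -75, v_t = -45, delta_t = 1.5,
                  v_reset = -60, v_peak = 0, refractory = 2)
  sw <- simulate_eif_sweep(p, protocol_descriptor("square_family", 120))
  ev <- detect_spikes(sw)
  expect_gt(nrow(ev), 0)
  # the 20 mV/ms criterion is met in the exponential upstroke a few mV above
  # v_t (where g_l*delta_t*exp((V - v_t)/delta_t) dominates the leak)
  expect_true(all(ev$threshold_v > p$v_t - 2 & ev$threshold_v < p$v_t + 10))
})

test_that("QC: drift and semilunar exclusion", {
  ok <- make_record(synth_rc_step_sweeps(10, noise_sd_mv = 0,
                                         baseline_offsets_mv = c(0, rep(2, 9))))
  q1 <- qc_cell(ok, list(r_in = 400))
  expect_true(q1$passed)
  expect_equal(q1$rmp_drift, 2, tolerance = 1e-9)

  drift <- make_record(synth_rc_step_sweeps(10, noise_sd_mv = 0,
                                            baseline_offsets_mv = c(0, rep(5, 9))))
  q2 <- qc_cell(drift, list(r_in = 400))
  expect_false(q2$passed)
  expect_match(q2$reasons, "drifted", all = FALSE)

  q3 <- qc_cell(ok, list(r_in = 85))
  expect_true(q3$excluded_as_semilunar)
  expect_false(q3$passed)
  expect_match(q3$reasons, "semilunar", all = FALSE)
})
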
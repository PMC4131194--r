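# Synthetic generators: EIF simulator against closed forms, curve archetypes,
# cohort structure and determinism.

test_that("EIF at rest stays at the leak reversal with no spikes", {
  p <- eif_params(delta_t = 1)
  sw <- simulate_eif_sweep(p, protocol_descriptor("square_family", 0,
                                                  duration_ms = 200))
  expect_length(attr(sw, "true_spike_times_ms"), 0)
  expect_equal(max(abs(sw$voltage - p$e_l)), 0, tolerance = 1e-9)
})

test_that("LIF limit reproduces the closed-form firing rate within 3%", {
  # R = 500 MOhm -> g_l = 2 nS; tau = 20 ms -> c_m = 40 pF
  p <- eif_params(c_m = 40, g_l = 2, e_l = -70, v_t = -50, delta_t = 0,
                  v_reset = -65, v_peak = 0, refractory = 0)
  proto <- protocol_descriptor("square_family", 60, duration_ms = 2000,
                               onset_ms = 0)
  sw <- simulate_eif_sweep(p, proto, tail_ms = 0)
  rate <- length(attr(sw, "true_spike_times_ms")) / 2
  analytic <- 1 / (0.02 * log(25 / 10))  # 54.57 Hz
  expect_equal(rate, analytic, tolerance = 0.03)
})

test_that("subthreshold EIF step obeys Ohm's law within 1%", {
  p <- eif_params(c_m = 20, g_l = 2, e_l = -75, v_t = -45, delta_t = 1)
  sweeps <- lapply(1:3, function(k)
    simulate_eif_sweep(p, protocol_descriptor("hyperpol_step", -10),
                       sweep_id = sprintf("h%d", k)))
  rin <- as.numeric(measure_input_resistance(sweeps))
  expect_equal(rin, 500, tolerance = 0.01)  # 1/g_l = 500 MOhm
})

test_that("curve generator: exact L archetype, S jump dominance, determinism", {
  # noise off, integer mean increment: statistics are exact
  k <- 4
  l <- generate_io_counts("L", 10, asl = k / sqrt(10), var = 0, jitter_sd = 0)
  st <- compute_io_statistics(l)
  expect_equal(st$asl_f, k / sqrt(10), tolerance = 1e-12)
  expect_identical(st$var_f, 0)

  s <- generate_io_counts("S", 10, asl = 2.4, var = 1.5, jitter_sd = 0)
  d <- diff(s$counts[s$included])
  expect_gt(max(d), 2 * median(d))  # one dominant jump

  a <- generate_io_counts("S", 20, asl = 2, var = 1, seed = 9)
  b <- generate_io_counts("S", 20, asl = 2, var = 1, seed = 9)
  expect_identical(a$counts, b$counts)
})

test_that("offset targeting moves the first suprathreshold amplitude", {
  lo <- generate_io_counts("L", 10, asl = 2, var = 0.5, offset_amp = 50,
                           jitter_sd = 0)
  hi <- generate_io_counts("L", 10, asl = 2, var = 0.5, offset_amp = 220,
                           jitter_sd = 0)
  expect_lt(compute_offset(lo), compute_offset(hi))
  expect_equal(compute_offset(hi), 200 / 10^0.25, tolerance = 1e-12)
})

test_that("p_linear_of_age is pinned, monotone, and balanced mid-range", {
  expect_identical(p_linear_of_age(21), 0.5 + 0.5 * (-1)^3)  # exactly 0
  expect_identical(p_linear_of_age(70), 1)
  expect_identical(p_linear_of_age(72), 1)
  ages <- 21:72
  expect_true(all(diff(p_linear_of_age(ages)) >= 0))
  expect_equal(p_linear_of_age(45.5), 0.5, tolerance = 1e-12)
})

test_that("endpoint-age cohorts are pure S (21 d) and pure L (70+ d)", {
  young <- generate_cohort(cohort_spec(n_cells = 30, seed = 40,
                                       age_range = c(21, 21)))
  expect_true(all(young$truth$group == "S"))
  old <- generate_cohort(cohort_spec(n_cells = 30, seed = 41,
                                     age_range = c(70, 72)))
  expect_true(all(old$truth$group == "L"))
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_spec(n_cells = 25, seed = 42))
  b <- generate_cohort(cohort_spec(n_cells = 25, seed = 42))
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$cells, function(x) x$curves[[1]]$counts),
                   lapply(b$cells, function(x) x$curves[[1]]$counts))
  expect_error(cohort_spec(n_cells = 10, seed = NULL), "requires a seed")
})

test_that("full pipeline on a generated cohort recovers the truth labels", {
  co <- generate_cohort(cohort_spec(n_cells = 120, seed = 43))
  ft <- cohort_features(co)
  km <- kmeans_two(ft$asl)
  acc <- max(mean((km$labels == "S") == (ft$group == "S")),
             mean((km$labels == "L") == (ft$group == "S")))
  expect_gte(acc, 0.95)
  # recovered centers within 5% of the generating means
  expect_equal(unname(km$centers["S"]), 2.409, tolerance = 0.05)
  expect_equal(unname(km$centers["L"]), 1.627, tolerance = 0.05)
})

test_that("S/L are separable by gain but not by the intrinsic parameters", {
  co <- generate_cohort(cohort_spec(n_cells = 120, seed = 44))
  ft <- cohort_features(co)
  ward <- ward_cluster_seven(ft, factor(ft$group, levels = c("S", "L")))
  expect_lt(ward$agreement$ari, 0.2)
})

test_that("tier-b record carries all protocols and survives feature extraction", {
  p <- eif_params(c_m = 30, g_l = 2, e_l = -76, v_t = -45, delta_t = 1.5,
                  v_reset = -58, v_peak = 0, refractory = 3)
  rec <- synth_cell_record(p, n_rin_sweeps = 5,
                           square_amps = seq(20, 120, 20),
                           frequencies = c(10, 20, 40),
                           sine_amps = seq(50, 300, 50), seed = 45)
  kinds <- vapply(rec$sweeps, function(s) s$protocol$kind, character(1))
  expect_setequal(unique(kinds), c("hyperpol_step", "square_family",
                                   "sine_family", "vc_step"))
  row <- compute_cell_features(rec)
  expect_equal(row$r_in, 500, tolerance = 0.02)
  expect_equal(row$c_m, 30, tolerance = 0.05)
  expect_true(row$qc_passed)
})
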
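# Constructed trace fixtures with known ground truth.

# Piecewise-linear spike waveform: rise of known slope (peak dV/dt) for
# 0.5 ms, linear repolarization over 2 ms. Spike time = start of the rise.
make_spike_trace <- function(spike_times_ms, dur_ms = 1000, sample_khz = 50,
                             baseline = -75, peak_dvdt = 150) {
  n <- round(dur_ms * sample_khz)
  t <- (seq_len(n) - 1) / sample_khz
  v <- rep(baseline, n)
  rise <- 0.5
  fall <- 2
  amp <- peak_dvdt * rise
  for (t0 in spike_times_ms) {
    up <- t >= t0 & t < t0 + rise
    dn <- t >= t0 + rise & t < t0 + rise + fall
    v[up] <- baseline + peak_dvdt * (t[up] - t0)
    v[dn] <- baseline + amp * (1 - (t[dn] - t0 - rise) / fall)
  }
  v
}

make_spike_sweep <- function(spike_times_ms, amplitude = 100, dur_ms = 1200,
                             sample_khz = 50, baseline = -75,
                             peak_dvdt = 150, sweep_id = "spk") {
  v <- make_spike_trace(spike_times_ms, dur_ms, sample_khz, baseline,
                        peak_dvdt)
  n <- length(v)
  i <- rep(0, n)
  proto <- protocol_descriptor("square_family", amplitude,
                               duration_ms = 1000, onset_ms = 100)
  i[window_ms(n, sample_khz, 100, 1100)] <- amplitude
  new_sweep(sweep_id, "current_clamp", sample_khz, v, i, proto)
}

window_ms <- function(n, rate, from, to) {
  idx <- seq_len(n)
  t <- (idx - 1) / rate
  idx[t >= from & t < to]
}

# square family with prescribed spike counts per amplitude
make_square_family <- function(counts, amp_start = 20, sample_khz = 50) {
  lapply(seq_along(counts), function(k) {
    cnt <- counts[k]
    times <- if (cnt > 0) seq(150, 1050, length.out = cnt) else numeric(0)
    make_spike_sweep(times, amplitude = amp_start + (k - 1) * 20,
                     sample_khz = sample_khz,
                     sweep_id = sprintf("sq%02d", k))
  })
}

# sine sweeps with prescribed spike counts, for build_io_curve fixtures
make_sine_sweeps <- function(frequency, amplitudes, counts, sample_khz = 50) {
  lapply(seq_along(amplitudes), function(k) {
    cnt <- counts[k]
    times <- if (cnt > 0) seq(150, 1050, length.out = cnt) else numeric(0)
    v <- make_spike_trace(times, dur_ms = 1200, sample_khz = sample_khz)
    n <- length(v)
    i <- rep(0, n)
    proto <- protocol_descriptor("sine_family", amplitudes[k],
                                 frequency = frequency, onset_ms = 100)
    tt <- (seq_len(n) - 1) / sample_khz
    stim <- tt >= 100 & tt < 1100
    i[stim] <- amplitudes[k] * sin(2 * pi * frequency * (tt[stim] - 100) / 1000)
    new_sweep(sprintf("sin_%d_%d", frequency, amplitudes[k]), "current_clamp",
              sample_khz, v, i, proto)
  })
}

# minimal valid record wrapping arbitrary sweeps
make_record <- function(sweeps, cell_id = "fix", age_days = 42,
                        labeled = TRUE) {
  cell_record(cell_id, "animal1", age_days = age_days, labeled = labeled,
              sweeps = sweeps)
}

# random but valid cell record for round-trip property tests
random_record <- function(id) {
  n_sw <- sample(2:4, 1)
  sweeps <- lapply(seq_len(n_sw), function(k) {
    kind <- sample(c("hyperpol_step", "sine_family", "vc_step"), 1)
    proto <- switch(kind,
      hyperpol_step = protocol_descriptor("hyperpol_step", -10),
      sine_family = protocol_descriptor("sine_family",
                                        sample(seq(50, 300, 50), 1),
                                        frequency = sample(c(5, 10, 20, 40, 60, 80), 1)),
      vc_step = protocol_descriptor("vc_step", -5, holding = -70))
    n <- sample(200:400, 1)
    new_sweep(sprintf("s%d", k),
              if (kind == "vc_step") "voltage_clamp" else "current_clamp",
              sample_rate = sample(c(20, 50), 1),
              voltage = round(rnorm(n, -70, 5), 4),
              current = round(rnorm(n, 0, 20), 4),
              proto, baseline_window = c(0, 2))
  })
  make_record(sweeps, cell_id = sprintf("cell%02d", id),
              age_days = sample(21:72, 1))
}
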
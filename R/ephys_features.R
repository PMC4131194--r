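# Intrinsic biophysical parameters and spike events from current-clamp and
# voltage-clamp sweeps, plus the QC exclusion rules.
#
# Conventions (units fixed package-wide): voltage mV, current pA, time ms,
# sample_rate kHz; hence MOhm = mV/pA * 1000, pF = (pA*ms)/mV.

# Zero-phase low-pass: 4th-order Butterworth magnitude response applied in
# the frequency domain after mirror padding. Zero phase by construction, so
# threshold-crossing times carry no filter latency.
lowpass_zero_phase <- function(v, sample_rate_khz, cutoff_khz = SPIKE_FILTER_KHZ,
                               order = 4) {
  n <- length(v)
  npad <- min(n - 1L, ceiling(5 * sample_rate_khz))  # 5 ms mirror pads
  x <- c(rev(v[2:(npad + 1L)]), v, rev(v[(n - npad):(n - 1L)]))
  m <- length(x)
  f <- c(0:(m %/% 2), -((m - m %/% 2 - 1L):1)) * (sample_rate_khz / m)
  H <- 1 / sqrt(1 + (f / cutoff_khz)^(2 * order))
  y <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / m
  y[(npad + 1L):(npad + n)]
}

# first derivative in mV/ms (central differences, one-sided at the ends)
dvdt_series <- function(v, sample_rate_khz) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * sample_rate_khz / 2
  d[1] <- (v[2] - v[1]) * sample_rate_khz
  d[n] <- (v[n] - v[n - 1]) * sample_rate_khz
  d
}

#' Detect action potentials in a current-clamp sweep
#'
#' A spike is an upward crossing of the derivative criterion (20 mV/ms) on the
#' 4 kHz zero-phase low-pass filtered voltage trace, deduplicated by a
#' refractory guard. The threshold voltage is the (filtered) voltage at the
#' crossing; the peak rate of rise is the maximum of the *unfiltered*
#' derivative within the event window.
#'
#' @param sweep a current-clamp [new_sweep()] sampled at >= 10 kHz.
#' @param dvdt_criterion derivative criterion, mV/ms.
#' @param refractory_ms minimum separation between events, ms.
#' @param event_window_ms window after the crossing searched for the peak
#'   rate of rise, ms.
#' @return data.frame with one row per spike: `time_ms`, `threshold_v`,
#'   `peak_dvdt`.
#' @export
detect_spikes <- function(sweep, dvdt_criterion = SPIKE_DVDT_CRITERION,
                          refractory_ms = 1, event_window_ms = 2) {
  if (!is_sweep(sweep)) stopf("sweep must be a gc_sweep")
  if (sweep$clamp_mode != "current_clamp")
    stopf("spike detection requires a current-clamp sweep")
  if (sweep$sample_rate < 10)
    stopf("sample rate %g kHz too low to resolve %g kHz filtering (need >= 10 kHz)",
          sweep$sample_rate, SPIKE_FILTER_KHZ)
  v <- sweep$voltage
  vf <- lowpass_zero_phase(v, sweep$sample_rate)
  df <- dvdt_series(vf, sweep$sample_rate)
  du <- dvdt_series(v, sweep$sample_rate)
  up <- which(df[-1] >= dvdt_criterion & df[-length(df)] < dvdt_criterion) + 1L
  if (!length(up))
    return(data.frame(time_ms = numeric(0), threshold_v = numeric(0),
                      peak_dvdt = numeric(0)))
  # a crossing within the refractory guard of the last kept event is the same
  # event and is dropped
  guard <- refractory_ms * sweep$sample_rate
  idx <- up[1]
  for (k in up[-1]) if (k - idx[length(idx)] >= guard) idx <- c(idx, k)
  win <- ceiling(event_window_ms * sweep$sample_rate)
  n <- length(v)
  peak <- vapply(seq_along(idx), function(k) {
    hi <- min(n, idx[k] + win)
    if (k < length(idx)) hi <- min(hi, idx[k + 1L] - 1L)
    max(du[idx[k]:hi])
  }, numeric(1))
  data.frame(time_ms = (idx - 1L) / sweep$sample_rate,
             threshold_v = vf[idx], peak_dvdt = peak)
}

# ---- hyperpolarizing-step machinery (Rin, tau, RMP) -------------------------

# steady-state window: last 20% of the step
step_windows <- function(sweep) {
  p <- sweep$protocol
  list(base = window_idx(sweep, sweep$baseline_window[1], sweep$baseline_window[2]),
       step = window_idx(sweep, p$onset_ms, p$onset_ms + p$duration_ms),
       ss = window_idx(sweep, p$onset_ms + 0.8 * p$duration_ms,
                       p$onset_ms + p$duration_ms))
}

# Flag sweeps carrying large spontaneous events: the residual of the
# baseline-subtracted trace against the pointwise median trace, smoothed over
# 2 ms so pointwise noise averages out while synaptic-scale transients
# (>= several ms) survive, exceeding `exclude_sd` robust SDs of the smoothed
# pooled baseline noise.
analyze_step_sweeps <- function(sweeps, exclude_sd = 5) {
  if (!length(sweeps)) stopf("no hyperpolarizing-step sweeps supplied")
  nmin <- min(vapply(sweeps, function(s) length(s$voltage), integer(1)))
  base_means <- vapply(sweeps, baseline_mean, numeric(1))
  sub <- vapply(seq_along(sweeps),
                function(i) sweeps[[i]]$voltage[1:nmin] - base_means[i],
                numeric(nmin))
  med <- apply(sub, 1, stats::median)
  base_idx <- step_windows(sweeps[[1]])$base
  noise <- stats::mad(as.numeric(sub[base_idx, ]) -
                        rep(med[base_idx], ncol(sub)))
  w <- max(1L, round(2 * sweeps[[1]]$sample_rate))  # 2 ms running mean
  kern <- rep(1 / w, w)
  sm <- apply(sub - med, 2, function(r) stats::filter(r, kern, sides = 2))
  smooth_max <- apply(abs(sm), 2, max, na.rm = TRUE)
  # robust SD of the smoothed baseline residuals, measured empirically so
  # correlated (membrane-filtered) noise is handled the same as white noise
  noise_sm <- stats::mad(sm[base_idx, ], na.rm = TRUE)
  # threshold = expected Gaussian extreme over the sweep plus exclude_sd
  # robust SDs, so clean noise never trips it while mV-scale synaptic
  # transients (which survive the 2 ms smoothing undiminished) always do
  allow <- sqrt(2 * log(nmin)) + exclude_sd
  accepted <- if (noise_sm > 0) smooth_max <= allow * noise_sm
              else rep(TRUE, length(sweeps))
  list(accepted = accepted, base_means = base_means, sub = sub, med = med,
       noise = noise)
}

#' Measure input resistance from small hyperpolarizing current steps
#'
#' Mean steady-state voltage deflection across accepted sweeps divided by the
#' step current. Sweeps carrying large spontaneous events (residual > 5 robust
#' SDs against the median trace) are excluded.
#'
#' @param sweeps list of `hyperpol_step` current-clamp sweeps (typically
#'   -10 pA).
#' @param exclude_sd exclusion criterion in robust SDs.
#' @return input resistance in MOhm, with attributes `n_used` and `excluded`
#'   (indices of rejected sweeps).
#' @export
measure_input_resistance <- function(sweeps, exclude_sd = 5) {
  an <- analyze_step_sweeps(sweeps, exclude_sd)
  if (!any(an$accepted)) stopf("all step sweeps excluded as contaminated")
  dv <- vapply(which(an$accepted), function(i) {
    w <- step_windows(sweeps[[i]])
    mean(sweeps[[i]]$voltage[w$ss]) - an$base_means[i]
  }, numeric(1))
  amp <- sweeps[[1]]$protocol$amplitude
  if (amp == 0) stopf("zero-amplitude step cannot yield a resistance")
  structure(mean(dv) / amp * 1000, n_used = sum(an$accepted),
            excluded = which(!an$accepted))
}

# single-exponential fit v ~ A*exp(-t/tau) + C on one segment; nls with a
# log-linear start, grid-search fallback
fit_single_exp <- function(t, v) {
  c0 <- v[length(v)]
  a0 <- v[1] - c0
  if (abs(a0) < 1e-12) stopf("flat segment: single-exponential fit failed")
  tau0 <- max((t[length(t)] - t[1]) / 4, 1e-3)
  fit <- tryCatch(
    stats::nls(v ~ A * exp(-t / tau) + C,
               start = list(A = a0, tau = tau0, C = c0),
               control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    tau <- coef(fit)[["tau"]]
    if (tau <= 0) fit <- NULL else
      return(list(tau = tau, resid = stats::resid(fit), fitted_amp = coef(fit)[["A"]]))
  }
  # fallback: profile tau on a grid, solve A, C linearly
  taus <- exp(seq(log(0.5), log(500), length.out = 300))
  sse <- vapply(taus, function(tau) {
    X <- cbind(exp(-t / tau), 1)
    sum(stats::lm.fit(X, v)$residuals^2)
  }, numeric(1))
  tau <- taus[which.min(sse)]
  X <- cbind(exp(-t / tau), 1)
  f <- stats::lm.fit(X, v)
  if (f$coefficients[1] * a0 < 0)
    stopf("non-decaying segment: single-exponential fit failed")
  list(tau = tau, resid = f$residuals, fitted_amp = f$coefficients[1])
}

#' Measure the membrane time constant
#'
#' Single-exponential fits on the averaged accepted trace, restricted to
#' 2-100 ms after the step onset and after the step offset; the two fitted
#' constants are averaged. A warning flags traces that a single exponential
#' describes poorly (structured residuals of non-negligible amplitude).
#'
#' @inheritParams measure_input_resistance
#' @param fit_window ms interval after onset/offset used for the fits.
#' @return time constant in ms, with attribute `per_segment` (onset, offset).
#' @export
measure_time_constant <- function(sweeps, exclude_sd = 5,
                                  fit_window = c(2, 100)) {
  an <- analyze_step_sweeps(sweeps, exclude_sd)
  if (!any(an$accepted)) stopf("all step sweeps excluded as contaminated")
  avg <- rowMeans(an$sub[, an$accepted, drop = FALSE])
  s1 <- sweeps[[1]]
  p <- s1$protocol
  rate <- s1$sample_rate
  seg <- function(t0) {
    idx <- window_idx(s1, t0 + fit_window[1], min(t0 + fit_window[2],
                                                  length(avg) / rate))
    tt <- (idx - 1) / rate - t0
    fit_single_exp(tt, avg[idx])
  }
  on <- seg(p$onset_ms)
  off <- seg(p$onset_ms + p$duration_ms)
  for (f in list(on, off)) {
    r <- f$resid
    if (length(r) > 2) {
      ac <- suppressWarnings(stats::cor(r[-1], r[-length(r)]))
      if (is.finite(ac) && ac > 0.9 && stats::sd(r) > 0.005 * abs(f$fitted_amp))
        warnf("trace poorly described by a single exponential (structured residuals); reported tau is a compromise")
    }
  }
  structure(mean(c(on$tau, off$tau)),
            per_segment = c(onset = on$tau, offset = off$tau))
}

#' Measure the resting membrane potential
#'
#' Mean pre-stimulus baseline voltage across accepted sweeps (same
#' spontaneous-event exclusion as [measure_input_resistance()]).
#'
#' @inheritParams measure_input_resistance
#' @return RMP in mV.
#' @export
measure_rmp <- function(sweeps, exclude_sd = 5) {
  an <- analyze_step_sweeps(sweeps, exclude_sd)
  if (!any(an$accepted)) stopf("all step sweeps excluded as contaminated")
  mean(an$base_means[an$accepted])
}

#' Measure whole-cell capacitance from a voltage-clamp step
#'
#' Charge of the capacitive transient (current integrated from the
#' steady-state level over the transient window) divided by the voltage step
#' amplitude: `Cm = |integral(I - I_ss) dt| / |dV|`, in pF.
#'
#' The transient window runs from the step onset until the current settles to
#' within 2 baseline-noise SDs of the steady state.
#'
#' @param sweep a `vc_step` voltage-clamp sweep (typically -5 mV from -70 mV).
#' @return capacitance in pF (0 with a warning when no transient is
#'   detectable).
#' @export
measure_capacitance <- function(sweep) {
  if (!is_sweep(sweep) || sweep$clamp_mode != "voltage_clamp" ||
      sweep$protocol$kind != "vc_step")
    stopf("capacitance requires a voltage-clamp vc_step sweep")
  p <- sweep$protocol
  i <- sweep$current
  rate <- sweep$sample_rate
  w <- step_windows(sweep)
  i_ss <- mean(i[w$ss])
  noise <- stats::sd(i[w$base])
  dev <- abs(i[w$step] - i_ss)
  thr <- max(2 * noise, 1e-9)
  if (max(dev) <= max(3 * noise, 1e-9)) {
    warnf("no detectable capacitive transient; returning 0 pF")
    return(0)
  }
  settle <- which(dev <= thr)
  end <- if (length(settle)) settle[1] else length(dev)
  seg <- (i[w$step] - i_ss)[1:end]
  q <- sum((seg[-1] + seg[-length(seg)]) / 2) / rate  # trapezoid, pA*ms = fC
  abs(q) / abs(p$amplitude)
}

#' Measure excitability features from a square-pulse family
#'
#' Action-potential threshold and peak rate of rise come from the first spike
#' elicited at the lowest spiking amplitude; the maximal firing rate is the
#' largest spike count across the 1 s sweeps before depolarization block.
#' Depolarization block is flagged at the first sweep whose count falls to
#' <= 75% of the running maximum as amplitude increases.
#'
#' @param sweeps list of `square_family` current-clamp sweeps.
#' @param block_frac fraction of the running-maximum count below which a sweep
#'   is treated as depolarization block.
#' @return list with `ap_threshold` (mV), `peak_dvdt` (mV/ms), `max_rate`
#'   (Hz), `counts` (per sweep, amplitude-ordered), `amplitudes` (pA) and
#'   `block_index` (NA if no block observed).
#' @export
measure_excitability <- function(sweeps, block_frac = 0.75) {
  if (!length(sweeps)) stopf("no square-family sweeps supplied")
  amps <- vapply(sweeps, function(s) s$protocol$amplitude, numeric(1))
  ord <- order(amps)
  sweeps <- sweeps[ord]; amps <- amps[ord]
  ev <- lapply(sweeps, detect_spikes)
  counts <- vapply(ev, nrow, integer(1))
  first <- which(counts > 0)[1]
  if (is.na(first)) stopf("no spiking sweep in the square family")
  run_max <- cummax(counts)
  blocked <- counts > 0 & counts <= block_frac * c(0, run_max[-length(run_max)])
  block_index <- which(blocked)[1]
  usable <- if (is.na(block_index)) seq_along(counts) else seq_len(block_index - 1L)
  dur_s <- sweeps[[1]]$protocol$duration_ms / 1000
  list(ap_threshold = ev[[first]]$threshold_v[1],
       peak_dvdt = ev[[first]]$peak_dvdt[1],
       max_rate = max(counts[usable]) / dur_s,
       counts = counts, amplitudes = amps, block_index = block_index)
}

#' Session quality control for one cell
#'
#' Computes the maximum drift of the per-sweep baseline potential relative to
#' the first sweep of the session, flags semilunar granule cells by their
#' extremely low input resistance, and combines both into a pass/fail verdict.
#'
#' @param record a [cell_record()].
#' @param passive list/row with at least `r_in` (MOhm); typically the output
#'   of the passive-feature measurements.
#' @param drift_max_mv tolerated resting-potential drift, mV.
#' @param semilunar_rin MOhm floor under which the cell is excluded as a
#'   semilunar granule cell.
#' @return list with `rmp_drift`, `passed`, `excluded_as_semilunar`,
#'   `reasons`.
#' @export
qc_cell <- function(record, passive, drift_max_mv = RMP_DRIFT_MAX_MV,
                    semilunar_rin = SEMILUNAR_RIN_MOHM) {
  cc <- Filter(function(s) s$clamp_mode == "current_clamp", record$sweeps)
  if (!length(cc)) stopf("cell %s: no current-clamp sweeps to monitor",
                         record$cell_id)
  baselines <- vapply(cc, baseline_mean, numeric(1))
  drift <- max(abs(baselines - baselines[1]))
  semilunar <- is.finite(passive$r_in) && passive$r_in < semilunar_rin
  reasons <- character(0)
  if (drift > drift_max_mv)
    reasons <- c(reasons, sprintf("resting potential drifted %.2f mV (> %g mV)",
                                  drift, drift_max_mv))
  if (semilunar)
    reasons <- c(reasons,
                 sprintf("input resistance %.0f MOhm < %g MOhm: semilunar granule cell",
                         passive$r_in, semilunar_rin))
  list(rmp_drift = drift, passed = drift <= drift_max_mv && !semilunar,
       excluded_as_semilunar = semilunar, reasons = reasons)
}
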
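# Ground-truthed synthetic data at two tiers:
#   (a) curve-level input-output counts (fast; used for population testing)
#   (b) trace-level exponential integrate-and-fire (EIF) sweeps under the
#       recording protocols, plus analytic RC fixtures with known R, tau, Cm.
# Truth (latent group, generating parameters, age) is always retained.

#' EIF model parameters
#'
#' @param c_m capacitance, pF. @param g_l leak conductance, nS.
#' @param e_l leak reversal (resting) potential, mV.
#' @param v_t threshold parameter, mV. @param delta_t spike sharpness, mV
#'   (0 selects the leaky integrate-and-fire limit).
#' @param v_reset post-spike reset, mV. @param v_peak spike cut-off, mV.
#' @param refractory absolute refractory period, ms.
#' @return an `gc_eif_params` list.
#' @export
eif_params <- function(c_m = 30, g_l = 2, e_l = -75, v_t = -45, delta_t = 2,
                       v_reset = -60, v_peak = 0, refractory = 2) {
  if (c_m <= 0 || g_l <= 0) stopf("c_m and g_l must be > 0")
  if (!(v_reset < v_t && v_t < v_peak))
    stopf("need v_reset < v_t < v_peak (got %g, %g, %g)", v_reset, v_t, v_peak)
  if (delta_t < 0 || refractory < 0) stopf("delta_t and refractory must be >= 0")
  structure(list(c_m = c_m, g_l = g_l, e_l = e_l, v_t = v_t,
                 delta_t = delta_t, v_reset = v_reset, v_peak = v_peak,
                 refractory = refractory), class = "gc_eif_params")
}

# command-current waveform for a current-clamp protocol, pA, sampled at dt ms
protocol_current <- function(protocol, dt, tail_ms = 100) {
  p <- protocol
  n <- round((p$onset_ms + p$duration_ms + tail_ms) / dt)
  t <- (seq_len(n) - 1) * dt
  stim <- t >= p$onset_ms & t < p$onset_ms + p$duration_ms
  i <- rep(p$holding, n)
  if (p$kind == "sine_family") {
    i[stim] <- p$holding +
      p$amplitude * sin(2 * pi * p$frequency * (t[stim] - p$onset_ms) / 1000)
  } else {
    i[stim] <- p$holding + p$amplitude
  }
  i
}

#' Simulate one current-clamp sweep of an EIF neuron
#'
#' Forward-Euler integration at `dt_ms` (default 0.02 ms, i.e. 50 kHz) of the
#' EIF membrane equation under a stimulation protocol. The returned sweep
#' carries the simulator's ground-truth spike times in attribute
#' `true_spike_times_ms`.
#'
#' @param params an [eif_params()].
#' @param protocol a current-clamp [protocol_descriptor()].
#' @param seed optional RNG seed.
#' @param dt_ms integration/sampling step, ms; must be <= 0.02.
#' @param noise_pa white current-noise SD, pA.
#' @param sweep_id identifier for the sweep.
#' @param tail_ms post-stimulus tail, ms.
#' @return a current-clamp [new_sweep()].
#' @export
simulate_eif_sweep <- function(params, protocol, seed = NULL, dt_ms = 0.02,
                               noise_pa = 0, sweep_id = "eif", tail_ms = 100) {
  stopifnot(inherits(params, "gc_eif_params"))
  if (!is_protocol(protocol) || protocol$kind == "vc_step")
    stopf("simulate_eif_sweep integrates current-clamp protocols only")
  if (dt_ms > 0.02 + 1e-12) stopf("integration step must be <= 0.02 ms")
  i_cmd <- protocol_current(protocol, dt_ms, tail_ms)
  res <- with_seed(seed,
    eif_integrate(i_cmd, dt_ms, params$c_m, params$g_l, params$e_l,
                  params$v_t, params$delta_t, params$v_reset, params$v_peak,
                  params$refractory, params$e_l, noise_pa))
  sw <- new_sweep(sweep_id, "current_clamp", 1 / dt_ms, res$voltage, i_cmd,
                  protocol)
  attr(sw, "true_spike_times_ms") <- res$spike_times_ms
  sw
}

#' Analytic RC current-clamp step sweeps with known ground truth
#'
#' Exponential charging responses of a passive RC membrane (resistance `r_in`
#' MOhm, time constant `tau_m` ms, resting potential `rmp` mV) to a current
#' step, with optional white voltage noise and optional injected synaptic-like
#' transients. These are the parameter-recovery fixtures for the passive
#' feature measurements.
#'
#' @param n_sweeps number of sweeps.
#' @param r_in MOhm. @param tau_m ms. @param rmp mV.
#' @param amplitude_pa step amplitude, pA. @param noise_sd_mv voltage noise SD.
#' @param sample_khz sampling rate.
#' @param onset_ms,duration_ms,tail_ms sweep layout.
#' @param transient_sweeps indices of sweeps that receive a +`transient_mv`
#'   synaptic-like transient in the response window.
#' @param transient_mv amplitude of the injected transient, mV.
#' @param baseline_offsets_mv optional per-sweep baseline shift (length
#'   `n_sweeps`), for drift fixtures.
#' @param seed optional RNG seed.
#' @return list of current-clamp sweeps.
#' @export
synth_rc_step_sweeps <- function(n_sweeps = 40, r_in = 300, tau_m = 30,
                                 rmp = -75, amplitude_pa = -10,
                                 noise_sd_mv = 0.2, sample_khz = 50,
                                 onset_ms = 100, duration_ms = 400,
                                 tail_ms = 150, transient_sweeps = integer(0),
                                 transient_mv = 5,
                                 baseline_offsets_mv = NULL, seed = NULL) {
  dv <- amplitude_pa * r_in / 1000  # steady-state deflection, mV
  n <- round((onset_ms + duration_ms + tail_ms) * sample_khz)
  t <- (seq_len(n) - 1) / sample_khz
  on <- t >= onset_ms & t < onset_ms + duration_ms
  after <- t >= onset_ms + duration_ms
  v0 <- rep(rmp, n)
  v0[on] <- rmp + dv * (1 - exp(-(t[on] - onset_ms) / tau_m))
  v_end <- rmp + dv * (1 - exp(-duration_ms / tau_m))
  v0[after] <- rmp + (v_end - rmp) * exp(-(t[after] - onset_ms - duration_ms) / tau_m)
  i_cmd <- rep(0, n)
  i_cmd[on] <- amplitude_pa
  if (is.null(baseline_offsets_mv)) baseline_offsets_mv <- rep(0, n_sweeps)
  proto <- protocol_descriptor("hyperpol_step", amplitude_pa,
                               duration_ms = duration_ms, onset_ms = onset_ms)
  with_seed(seed, lapply(seq_len(n_sweeps), function(k) {
    v <- v0 + baseline_offsets_mv[k] +
      if (noise_sd_mv > 0) stats::rnorm(n, 0, noise_sd_mv) else 0
    if (k %in% transient_sweeps) {
      # alpha-shaped depolarizing transient mid-step
      t0 <- onset_ms + duration_ms / 2
      tt <- pmax(t - t0, 0)
      v <- v + transient_mv * (tt / 5) * exp(1 - tt / 5)
    }
    new_sweep(sprintf("rc_%03d", k), "current_clamp", sample_khz, v, i_cmd,
              proto)
  }))
}

#' Analytic voltage-clamp capacitance-test sweep
#'
#' Recorded current of a series-resistance + RC membrane under a voltage step:
#' instantaneous jump `dV/Rs` decaying with `tau = Cm * Rs * Rm / (Rs + Rm)`
#' to the steady state `dV / (Rs + Rm)`. With small `Rs` the integral of the
#' transient equals `Cm * dV * (Rm / (Rs + Rm))^2`, so the charge-based
#' estimate recovers `c_m` up to that known factor.
#'
#' @param c_m pF. @param r_m membrane resistance, MOhm. @param r_s access
#'   resistance, MOhm. @param delta_v step amplitude, mV. @param holding mV.
#' @param sample_khz sampling rate. @param noise_sd_pa current noise SD.
#' @param seed optional RNG seed.
#' @return a voltage-clamp sweep.
#' @export
synth_vc_cap_sweep <- function(c_m = 25, r_m = 500, r_s = 2, delta_v = -5,
                               holding = -70, sample_khz = 50,
                               noise_sd_pa = 0, seed = NULL) {
  proto <- protocol_descriptor("vc_step", delta_v, duration_ms = 100,
                               onset_ms = 50, holding = holding)
  n <- round((proto$onset_ms + proto$duration_ms + 50) * sample_khz)
  t <- (seq_len(n) - 1) / sample_khz
  on <- t >= proto$onset_ms & t < proto$onset_ms + proto$duration_ms
  tau <- c_m * r_s * r_m / (r_s + r_m) / 1000  # MOhm*pF = us -> ms
  i_ss <- delta_v / (r_s + r_m) * 1000         # mV/MOhm = nA -> pA
  i_peak <- delta_v / r_s * 1000
  i <- rep(0, n)
  i[on] <- i_ss + (i_peak - i_ss) * exp(-(t[on] - proto$onset_ms) / tau)
  # step offset transient (discharging), same time constant
  after <- t >= proto$onset_ms + proto$duration_ms
  i[after] <- -(i_peak - i_ss) * exp(-(t[after] - proto$onset_ms -
                                         proto$duration_ms) / tau)
  v_cmd <- rep(holding, n)
  v_cmd[on] <- holding + delta_v
  i <- with_seed(seed, i + if (noise_sd_pa > 0) stats::rnorm(n, 0, noise_sd_pa) else 0)
  new_sweep("vc_cap", "voltage_clamp", sample_khz, v_cmd, i, proto)
}

# ---- curve-level generator (tier a) ----------------------------------------

# deterministic increment shapes with sample mean 0 and sample variance 1:
# L spreads the variance evenly (alternating), S concentrates it in one
# dominant jump (sensitivity to a narrow input range)
increment_pattern <- function(group, m) {
  base <- if (group == "S") {
    v <- rep(-1, m)
    v[ceiling(m / 2)] <- m - 1
    v
  } else {
    rep_len(c(-1, 1), m)
  }
  e <- base - mean(base)
  e / stats::sd(e)
}

#' Generate one synthetic input-output curve
#'
#' Constructs integer spike counts over the amplitude grid whose included
#' increments realize the requested frequency-weighted slope statistics:
#' mean increment `asl * sqrt(f)`, increment variance `var * f`. The S
#' archetype concentrates the variance in one dominant jump; the L archetype
#' spreads increments evenly. Counts cross `f/2` at the amplitude nearest
#' `offset_amp` (leading amplitudes below it stay at zero), and Poisson-like
#' jitter perturbs the increments before rounding.
#'
#' @param group `"S"` or `"L"`.
#' @param frequency sinusoid frequency, Hz.
#' @param asl,var target frequency-weighted statistics of the cell.
#' @param offset_amp target offset amplitude, pA.
#' @param amplitudes amplitude grid, pA.
#' @param jitter_sd SD of the additive increment jitter (0 = noise off).
#' @param seed optional RNG seed.
#' @return a masked `gc_io_curve`.
#' @export
generate_io_counts <- function(group = c("S", "L"), frequency, asl, var,
                               offset_amp = 50,
                               amplitudes = seq(50, 450, by = 50),
                               jitter_sd = 0.5, seed = NULL) {
  group <- match.arg(group)
  if (!(frequency %in% SINE_FREQUENCIES_HZ)) stopf("frequency off grid")
  if (asl <= 0 || var < 0) stopf("asl must be > 0 and var >= 0")
  n_amp <- length(amplitudes)
  n_lead <- min(max(round(offset_amp / SINE_AMP_STEP_PA) - 1, 0), n_amp - 5L)
  m <- n_amp - n_lead - 1L
  mu_d <- asl * sqrt(frequency)
  e <- increment_pattern(group, m)
  d <- mu_d + sqrt(var * frequency) * e
  d <- with_seed(seed, d + if (jitter_sd > 0) stats::rnorm(m, 0, jitter_sd) else 0)
  d <- pmax(1, round(d))
  c0 <- floor(frequency / 2) + 1  # smallest count strictly above f/2
  counts <- c(rep(0, n_lead), c0 + c(0, cumsum(d)))
  mask_io_curve(io_curve(frequency, amplitudes, counts))
}

# ---- cohort specification and generation ------------------------------------

#' Specify a synthetic neuron cohort
#'
#' Defaults encode the stated world: ages uniform over 21-72 days
#' postmitotic; the probability of the Linear state pinned to 0 at 21 d and 1
#' at 70 d with a gentle mid-range slope (both groups coexist across weeks
#' 5-9); passive properties drifting continuously with age and independent of
#' the functional group; pooled gain centers at the published K-means centers
#' (ASL 2.409/1.627, VAR 1.536/0.659 for S/L). Within the L group the gain
#' tracks input resistance; within the S group it does not; the offset scales
#' with 1/r_in in both groups.
#'
#' @param n_cells cohort size.
#' @param seed RNG seed (required for reproducible truth).
#' @param age_range days postmitotic, inclusive.
#' @param asl_S,asl_S_sd,asl_L,asl_L_sd group ASL means and residual SDs.
#' @param var_S,var_S_sd,var_L,var_L_sd group VAR means and residual SDs.
#' @param asl_L_rin_coef,var_L_rin_coef L-group dependence of the gain on the
#'   standardized log input resistance (per SD).
#' @param offset_scale offset amplitude = `offset_scale / r_in` pA (both
#'   groups), with lognormal jitter `offset_jitter`.
#' @param rin_range MOhm at the young/old ends of the age range (log-linear
#'   drift). @param rin_cv lognormal CV of r_in.
#' @param cm_range pF at the young/old ends. @param cm_cv lognormal CV.
#' @param rmp_range,thr_range,dvdt_range,maxrate_range young/old endpoint
#'   means of RMP (mV), AP threshold (mV), peak dV/dt (mV/ms), maximal rate
#'   (Hz). @param rmp_sd,thr_sd,dvdt_sd,maxrate_sd their SDs.
#' @param unimodal if TRUE, a single-population control cohort: every cell's
#'   gain is drawn from one Gaussian (`uni_asl_mean`/`uni_asl_sd`, similarly
#'   VAR) with no r_in coupling.
#' @param uni_asl_mean,uni_asl_sd,uni_var_mean,uni_var_sd unimodal control
#'   parameters.
#' @param frequencies sinusoid frequencies generated per cell.
#' @param amplitudes amplitude grid per curve.
#' @param jitter_sd increment jitter of [generate_io_counts()].
#' @return a `gc_cohort_spec` list.
#' @export
cohort_spec <- function(n_cells = 120, seed = DEFAULT_SEED,
                        age_range = c(21L, 72L),
                        asl_S = 2.409, asl_S_sd = 0.18,
                        asl_L = 1.627, asl_L_sd = 0.134, asl_L_rin_coef = 0.12,
                        var_S = 1.536, var_S_sd = 0.251,
                        var_L = 0.659, var_L_sd = 0.13, var_L_rin_coef = 0.10,
                        offset_scale = 45000, offset_jitter = 0.15,
                        rin_range = c(4000, 300), rin_cv = 0.15,
                        cm_range = c(15, 60), cm_cv = 0.10,
                        rmp_range = c(-62, -83), rmp_sd = 3,
                        thr_range = c(-35, -45), thr_sd = 2,
                        dvdt_range = c(120, 480), dvdt_sd = 30,
                        maxrate_range = c(25, 120), maxrate_sd = 10,
                        unimodal = FALSE,
                        uni_asl_mean = 2.0, uni_asl_sd = 0.3,
                        uni_var_mean = 1.0, uni_var_sd = 0.3,
                        frequencies = SINE_FREQUENCIES_HZ,
                        amplitudes = seq(50, 450, by = 50),
                        jitter_sd = 0.5) {
  if (is.null(seed)) stopf("cohort_spec requires a seed")
  if (n_cells < 1) stopf("n_cells must be >= 1")
  if (age_range[1] < 21 || age_range[2] > 72 || age_range[1] > age_range[2])
    stopf("age_range must lie within [21, 72] days")
  spec <- as.list(environment())
  structure(spec, class = "gc_cohort_spec")
}

#' Probability of the Linear state as a function of age
#'
#' Monotone, pinned to 0 at 21 days and 1 at 70 days:
#' `p_L = 0.5 + 0.5 * (2t - 1)^3` with `t = clamp((age - 21) / 49, 0, 1)`.
#' The cubic keeps the mid-range slope gentle so that both functional groups
#' coexist across weeks 5-9.
#'
#' @param age_days numeric vector of ages.
#' @return probabilities in \[0, 1\].
#' @export
p_linear_of_age <- function(age_days) {
  t <- pmin(pmax((age_days - 21) / 49, 0), 1)
  u <- 2 * t - 1
  0.5 + 0.5 * u^3
}

#' Generate a synthetic cohort with retained ground truth
#'
#' Draws per-cell age, latent S/L group from [p_linear_of_age()], passive
#' properties from the age-drift distributions (group-independent, so the
#' seven intrinsic parameters do not encode the group), gain targets per the
#' group model, and emits curve-level input-output data via
#' [generate_io_counts()].
#'
#' @param spec a [cohort_spec()].
#' @return a `gc_cohort` list: `cells` (each with `curves` and `truth`),
#'   `truth` (data.frame, one row per cell) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "gc_cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cells
    age <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
    t <- (age - 21) / 49
    p_l <- p_linear_of_age(age)
    group <- ifelse(stats::runif(n) < p_l, "L", "S")
    r_in <- exp(lerp(log(spec$rin_range[1]), log(spec$rin_range[2]), t) +
                  stats::rnorm(n, 0, spec$rin_cv))
    c_m <- exp(lerp(log(spec$cm_range[1]), log(spec$cm_range[2]), t) +
                 stats::rnorm(n, 0, spec$cm_cv))
    tau_m <- r_in * c_m / 1000 * exp(stats::rnorm(n, 0, 0.05))
    rmp <- lerp(spec$rmp_range[1], spec$rmp_range[2], t) +
      stats::rnorm(n, 0, spec$rmp_sd)
    thr <- lerp(spec$thr_range[1], spec$thr_range[2], t) +
      stats::rnorm(n, 0, spec$thr_sd)
    dvdt <- pmax(lerp(spec$dvdt_range[1], spec$dvdt_range[2], t) +
                   stats::rnorm(n, 0, spec$dvdt_sd), 25)
    maxrate <- pmax(lerp(spec$maxrate_range[1], spec$maxrate_range[2], t) +
                      stats::rnorm(n, 0, spec$maxrate_sd), 1)
    # standardized log input resistance against the fixed drift midline
    z_rin <- (log(r_in) - mean(log(spec$rin_range))) /
      (abs(diff(log(spec$rin_range))) / sqrt(12))
    if (spec$unimodal) {
      asl_t <- pmax(stats::rnorm(n, spec$uni_asl_mean, spec$uni_asl_sd), 0.3)
      var_t <- pmax(stats::rnorm(n, spec$uni_var_mean, spec$uni_var_sd), 0.05)
    } else {
      # the L cells skew old (lower r_in), so the r_in term is centered on the
      # realized L-cell mean: the L-group mean lands on asl_L by construction
      # while the within-group r_in dependence is preserved
      zl <- z_rin - mean(z_rin[group == "L"])
      asl_t <- ifelse(group == "S",
                      stats::rnorm(n, spec$asl_S, spec$asl_S_sd),
                      spec$asl_L + spec$asl_L_rin_coef * zl +
                        stats::rnorm(n, 0, spec$asl_L_sd))
      var_t <- ifelse(group == "S",
                      stats::rnorm(n, spec$var_S, spec$var_S_sd),
                      spec$var_L + spec$var_L_rin_coef * zl +
                        stats::rnorm(n, 0, spec$var_L_sd))
      asl_t <- pmax(asl_t, 0.3)
      var_t <- pmax(var_t, 0.05)
    }
    offset_amp <- spec$offset_scale / r_in *
      exp(stats::rnorm(n, 0, spec$offset_jitter))
    truth <- data.frame(
      cell_id = sprintf("syn%03d", seq_len(n)), age_days = age, group = group,
      r_in = r_in, tau_m = tau_m, c_m = c_m, rmp = rmp, ap_threshold = thr,
      peak_dvdt = dvdt, max_rate = maxrate, asl_true = asl_t,
      var_true = var_t, offset_amp = offset_amp, stringsAsFactors = FALSE)
    cells <- lapply(seq_len(n), function(i) {
      curves <- lapply(spec$frequencies, function(f)
        generate_io_counts(group[i], f, asl_t[i], var_t[i], offset_amp[i],
                           spec$amplitudes, spec$jitter_sd))
      list(curves = curves, truth = truth[i, ])
    })
    structure(list(cells = cells, truth = truth, spec = spec),
              class = "gc_cohort")
  })
}

#' @export
print.gc_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort: %d cells (%d S / %d L), seed %d>\n",
              nrow(x$truth), sum(x$truth$group == "S"),
              sum(x$truth$group == "L"), x$spec$seed))
  invisible(x)
}

#' Per-cell feature table of a synthetic cohort
#'
#' Runs the input-output feature extraction on every cell's curves and carries
#' the generated intrinsic parameters through as the cell's measured values
#' (curve-level cohorts have no traces to re-measure them from).
#'
#' @param cohort a `gc_cohort`.
#' @return data.frame with one row per cell: identifiers, age, pooled
#'   `asl`/`var`/`offset_norm`, the seven intrinsic parameters, `incomplete`
#'   and `qc_passed` flags, and the truth `group`.
#' @export
cohort_features <- function(cohort) {
  stopifnot(inherits(cohort, "gc_cohort"))
  io <- lapply(cohort$cells, function(cl) pool_features(cl$curves))
  data.frame(
    cohort$truth[c("cell_id", "age_days", "r_in", "tau_m", "c_m", "rmp",
                   "ap_threshold", "peak_dvdt", "max_rate")],
    asl = vapply(io, `[[`, numeric(1), "asl"),
    var = vapply(io, `[[`, numeric(1), "var"),
    offset_norm = vapply(io, `[[`, numeric(1), "offset_norm"),
    incomplete = vapply(io, `[[`, logical(1), "incomplete"),
    qc_passed = TRUE,
    group = cohort$truth$group,
    stringsAsFactors = FALSE)
}

#' Build a trace-level (tier b) cell record from an EIF model
#'
#' Emits a full protocol set for one model cell: hyperpolarizing -10 pA steps,
#' a square family up to depolarization-test amplitudes, sinusoid families at
#' the requested frequencies/amplitudes, and an analytic voltage-clamp
#' capacitance test. Intended for fixture-scale use (a few cells); curve-level
#' cohorts are the fast tier.
#'
#' @param params an [eif_params()].
#' @param cell_id,age_days,labeled record identity.
#' @param n_rin_sweeps number of -10 pA step sweeps.
#' @param square_amps square-family amplitudes, pA.
#' @param frequencies,sine_amps sinusoid grid.
#' @param noise_pa current-noise SD for the simulated sweeps.
#' @param seed RNG seed.
#' @return a [cell_record()] whose attribute `eif_params` retains the truth.
#' @export
synth_cell_record <- function(params, cell_id = "eif_cell", age_days = 42,
                              labeled = TRUE, n_rin_sweeps = 10,
                              square_amps = seq(20, 200, by = 20),
                              frequencies = SINE_FREQUENCIES_HZ,
                              sine_amps = seq(50, 450, by = 50),
                              noise_pa = 0, seed = DEFAULT_SEED) {
  stopifnot(inherits(params, "gc_eif_params"))
  with_seed(seed, {
    sweeps <- list()
    for (k in seq_len(n_rin_sweeps))
      sweeps[[length(sweeps) + 1L]] <- simulate_eif_sweep(
        params, protocol_descriptor("hyperpol_step", -10),
        noise_pa = noise_pa, sweep_id = sprintf("rin_%02d", k))
    for (a in square_amps)
      sweeps[[length(sweeps) + 1L]] <- simulate_eif_sweep(
        params, protocol_descriptor("square_family", a),
        noise_pa = noise_pa, sweep_id = sprintf("sq_%03d", a))
    for (f in frequencies) for (a in sine_amps)
      sweeps[[length(sweeps) + 1L]] <- simulate_eif_sweep(
        params, protocol_descriptor("sine_family", a, frequency = f),
        noise_pa = noise_pa, sweep_id = sprintf("sin_%02d_%03d", f, a))
    sweeps[[length(sweeps) + 1L]] <- synth_vc_cap_sweep(
      c_m = params$c_m, r_m = 1000 / params$g_l)
    rec <- cell_record(cell_id, "synthetic", age_days = age_days,
                       labeled = labeled, sweeps = sweeps,
                       notes = "synthetic EIF cell")
    attr(rec, "eif_params") <- params
    rec
  })
}
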
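---
title: "Two input-output states of maturing granule cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two input-output states of maturing granule cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcio)
```

## The problem and the model

Adult-born granule cells (ABGCs) of the dentate gyrus are recorded in current
clamp at known postmitotic ages (21–72 days). Their passive properties mature
continuously, so none of the classic biophysical parameters partitions a
cohort into discrete classes. The quantity that does is the *gain of the
input–output function* under sinusoidal drive: 1 s sinusoids at 5, 10, 20,
40, 60 and 80 Hz are injected at peak amplitudes increasing in 50 pA steps,
and the spike count per sweep is read out as a function of amplitude.

With `d` the successive count increments over the included part of one
curve at frequency `f`, the package computes

* `asl_f = mean(d) / sqrt(f)` — average slope (gain),
* `var_f = Var(d) / f` — variance of the increments (sample, n−1),
* `offset_f = A* / f^(1/4)` — `A*` the smallest amplitude whose count
  strictly exceeds `f/2`,

and pools each statistic across frequencies by the arithmetic mean of its
defined per-frequency values (at least three frequencies required, otherwise
the cell is flagged incomplete). Cells separate into a *Sensitive* group
(high ASL, high VAR: most of the output dynamic range is traversed within one
or two input steps) and a *Linear* group (constant increments).

### Choices the definitions leave open

* **Direction of the frequency weighting.** "Weighted by the square root of
  the frequency" does not say multiply or divide. The package *divides*
  (`mean(d)/sqrt(f)`, `Var(d)/f`, `A*/f^(1/4)`): spike counts grow with drive
  frequency, so division compresses that growth into a frequency-independent
  per-cell number, and it is the only direction that reproduces the printed
  magnitudes of the cluster centers (ASL ≈ 1.6 and 2.4).
* **Increment units.** Increments are per 50 pA grid step, not per pA,
  matching how the curves are plotted and keeping ASL of order 1.
* **Variance estimator.** The sample (n−1) estimator.
* **Offset comparison.** Strict (`>`), i.e. the output rate must *exceed*
  half the input frequency.
* **Pooling.** The unweighted mean of already-weighted per-frequency values.
  The original "empirically determined correlations" procedure is not
  recoverable from any published material.

### Lack/saturation masking

The included run of a curve drops leading zero counts (lack of spiking) and
truncates from the first amplitude whose count fails to exceed the previous
included count (saturation onset). If that leaves fewer than three points,
the longest maximal strictly increasing run of positive counts is used
instead when one of length ≥ 3 exists (earliest on ties); otherwise the
curve contributes no slope statistics at that frequency. Masking is
idempotent, and offsets are computed from the unmasked counts (leading
"lack" points are zeros and cannot satisfy the criterion anyway).

## Feature extraction conventions

All units are fixed package-wide: mV, pA, kHz, ms (so MΩ = mV/pA·10³ and
pF = pA·ms/mV).

* **Spikes**: upward crossings of 20 mV/ms in the derivative of the 4 kHz
  low-pass filtered voltage. The filter is a zero-phase 4th-order Butterworth
  magnitude response applied in the frequency domain with mirror padding —
  zero-phase so the reported threshold voltage carries no filter latency.
  Events within a 1 ms refractory guard collapse onto their first crossing.
  Peak dV/dt is taken from the *unfiltered* derivative in a 2 ms event
  window. Sampling below 10 kHz cannot support the 4 kHz cutoff and errors.
* **R_in**: mean steady-state deflection (last 20% of the step) of −10 pA
  step sweeps divided by the step current. Sweeps with large spontaneous
  events are excluded: the residual against the pointwise median trace,
  smoothed over 2 ms, must stay below `sqrt(2 log n) + 5` robust SDs of the
  smoothed baseline noise. The extreme-value allowance keeps clean noise
  (white or membrane-filtered) below threshold across a full sweep while
  mV-scale synaptic transients, which survive 2 ms smoothing undiminished,
  exceed it by an order of magnitude. The published criterion gives no
  operational rule; this one is parameter-free at the user level.
* **τ_M**: single-exponential fits restricted to 2–100 ms after step onset
  and after step offset, averaged. `nls` with a log-linear start, and a
  tau-profiled grid search as fallback. Structured residuals of
  non-negligible amplitude (lag-1 autocorrelation > 0.9 and residual SD
  > 0.5% of the fitted amplitude) flag traces a single exponential describes
  poorly; the value is still returned as the documented compromise.
* **C_m**: `|∫(I − I_ss) dt| / |ΔV|` over the transient window of a −5 mV
  voltage-clamp step, the window ending where the current settles within two
  baseline-noise SDs of steady state.
* **Excitability**: threshold and peak dV/dt from the first spike at the
  lowest spiking amplitude of the Δ20 pA square family; maximal rate is the
  largest 1 s count before depolarization block. Block is operationalized as
  the first sweep whose count falls to ≤ 75% of the running maximum — the
  50% rule first considered proved inconsistent with the intended behavior
  on curves such as counts (…, 55, 40), where the drop to 40 should mark
  block; 75% marks it while still tolerating ordinary count jitter.
* **QC**: maximum per-sweep baseline deviation from the first sweep > 4 mV
  fails the session; R_in < 90 MΩ excludes the cell as a semilunar granule
  cell. Both thresholds are exported constants.

## Population inference

* **One vs two Gaussians.** Histograms use the Freedman–Diaconis bin width
  with a floor of 12 bins — below that the 6-parameter two-component curve is
  not identifiable (FD alone can give 4–7 bins at n = 120). One and two
  scaled Gaussians are fitted by bounded least squares from multiple starts
  (including the nested start, so the two-component SSE can never exceed the
  one-component SSE), and summarized by the extra-sum-of-squares F statistic.
  The *decision* p-value, however, comes from a parametric-bootstrap
  likelihood-ratio test: EM mixture fit on the raw values, with the LRT
  statistic calibrated against 120 bootstrap cohorts drawn from the fitted
  single Gaussian. Mixture comparisons are non-regular, and simulation during
  development showed the analytic F reference is both underpowered on the
  histogram and anticonservative under unimodal truth (≈ 25% false
  two-preference at the 0.05 level); the bootstrap LRT is calibrated by
  construction and is the standard remedy. Two components are preferred when
  the bootstrap p < 0.05. Printed `F = 0.0014`-style values in the source
  material are read as p-values (their magnitudes are incompatible with F
  statistics); the package reports statistic and p separately.
* **K-means** with k = 2 and 25 restarts under a fixed seed (default
  20140724) on one statistic at a time; the higher-gain cluster is S.
  Separation is summarized by a one-way ANOVA p-value. Cluster centers and
  the mean absolute distance from center per cluster mirror the printed
  summaries.
* **Ward clustering** (`ward.D2`, Euclidean) on the seven z-scored intrinsic
  parameters, cut at two clusters; agreement against the functional labels is
  reported as best-permutation accuracy and adjusted Rand index (the original
  "did not match" is not operationalized anywhere, so both standard
  agreement measures are given).
* **Age structure**: weekly bins by `floor(age_days/7)` (weeks 3–10), S/L
  fractions per bin; per-bin mean and variance of the statistic fitted with a
  quadratic (variance on mean) — a two-group mixture makes the variance peak
  at transition ages, `Var = w(1−w)Δμ² + …`. Exact 3-bin fits have zero
  residual degrees of freedom and return an undefined p with a note.
* **Correlations**: OLS of each gain statistic on R_in within S, within L,
  and pooled; adjusted R² (which can legitimately be negative on null data)
  and the slope t-test p.

## The synthetic cohort: a stated world

No recordings are deposited, so every quantitative test runs against a
generator whose defaults *are* the stated world:

* ages uniform on 21–72 days postmitotic;
* probability of the Linear state pinned to 0 at 21 d and 1 at 70 d,
  `p_L = 0.5 + 0.5(2t−1)³` with `t = (age−21)/49` clamped to [0, 1]. The
  cubic was chosen at design time: hard pins at the ends (the youngest cells
  are all S, the oldest all L) with a gentle mid-range slope so both groups
  coexist across weeks 5–9. A steep transition would make age — and hence the
  age-drifting intrinsic parameters — predictive of the functional group,
  contradicting the qualitative target that Ward clustering on intrinsic
  parameters sits near chance;
* passive drift, group-independent: R_in log-linear from ~4 GΩ (young) to
  ~300 MΩ (mature) with 15% lognormal scatter; C_m 15→60 pF; τ_M = R_in·C_m
  with 5% jitter; RMP −62→−83 mV; threshold −35→−45 mV; peak dV/dt
  120→480 mV/ms; maximal rate 25→120 Hz. These endpoint magnitudes are
  plausible granule-cell values chosen by the implementer — the source shows
  them only graphically — and are fixtures, not facts;
* pooled gain centers at the published K-means centers (ASL 2.409/1.627,
  VAR 1.536/0.659 for S/L, SDs ≈ 0.18/0.25); within the L group the gain
  depends on the standardized log input resistance (coefficient 0.12 per SD,
  centered on the realized L-cell mean so the group mean lands on its target
  despite L cells skewing old), within S it does not; the offset amplitude is
  `45000 pA·MΩ / R_in` in both groups with 15% lognormal jitter;
* curve-level counts realize a cell's (asl, var) targets exactly up to
  integer rounding: a deterministic increment pattern with unit sample
  variance — one dominant jump for S, alternating for L — scaled to mean
  `asl·√f` and variance `var·f`, plus N(0, 0.5²) increment jitter, counts
  crossing `f/2` at the amplitude nearest the cell's offset target.

A trace-level tier simulates full protocol sets through an exponential
integrate-and-fire membrane (`C dV/dt = −g_L(V−E_L) + g_L Δ_T
exp((V−V_T)/Δ_T) + I(t)`), forward-Euler at 0.02 ms in compiled code, with
`Δ_T = 0` selecting the leaky integrate-and-fire limit. The simulator is
validated against the closed-form LIF rate (≤ 3%) and Ohm's law (≤ 1%), and
its ground-truth spike times ride along on every sweep. Deterministic EIF
cells phase-lock to sinusoids (count plateaus at integer ratios of the drive
frequency); adding ~25 pA white current noise — physiologically sensible —
breaks the locking and yields the graded curves the masking rules expect.

What a green test does **not** establish: the generator reproduces the
*dependence structure* of the published cohort, not its raw data. Real
recordings add serial correlations, electrode drift, seal nonstationarity and
cell-to-cell protocol differences that the generator does not emulate; the
acceptance suite therefore checks recovery, calibration and invariants, never
agreement with published point estimates.

## Numerical choices and degenerate inputs

* On-disk series are written at 9 significant digits; decimal → double →
  decimal round-trips are exact at that precision, making rewrite
  byte-identical (the round-trip oracle in the tests).
* All stochastic steps run under explicit seeds; `with_seed()` restores the
  caller's RNG state, so library calls never perturb a user's stream.
  Reports are written with fixed 12-significant-digit formatting, making
  whole report bundles byte-identical across reruns of one config+seed.
* Degenerate cases are contracts, not accidents: all-equal values error in
  K-means ("no separation"); σ → 0 in mixture fits is prevented by bounds
  (σ ≥ spread/100 in least squares, σ ≥ s/30 in EM); a zero capacitive
  transient returns 0 pF with a warning; an undefined input–output curve
  propagates as missing and, with fewer than three defined frequencies,
  flags the cell incomplete rather than silently pooling.
* The CSV+JSON bundle (one diffable CSV per sweep plus a manifest with
  explicit units) is the canonical container; HDF5 support is provided
  opportunistically through rhdf5 when installed. NWB import is not included:
  no NWB reader exists in the supported dependency set, and a partial
  hand-rolled one would be worse than a clear error.

## Known limitations

* The pooling rule and the weighting direction are reconstructions of an
  under-specified procedure; both are documented above and isolated in
  `compute_io_statistics()` / `pool_features()` should either ever need to
  change.
* Depolarization-block detection (75% rule) and the spontaneous-event
  exclusion are operationalizations of criteria the source states only
  verbally.
* The EIF tier models the S/L phenomenology through threshold sharpness and
  noise, one of several conductance-level mechanisms consistent with the
  data; it makes no claim about the biological substrate.
* Tier-a cohorts carry their generated intrinsic parameters directly into
  the feature table (there are no traces to re-measure them from); tier-b
  records exercise the full measurement path but are fixture-scale.
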
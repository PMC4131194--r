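# gcio — input–output gain analysis of adult-born dentate granule cells

Adult-born granule cells (ABGCs) of the dentate gyrus mature over weeks, and
their passive membrane properties (input resistance, time constant,
capacitance, resting potential) drift continuously with cell age. Their
*input–output transformation* does not: when driven with sinusoidal currents
of increasing peak amplitude, individual cells fall into one of two discrete
functional states — a **Sensitive (S)** state with a steep, highly variable
spike-count gain concentrated in a narrow input range, and a **Linear (L)**
state whose spike output grows by a near-constant increment per input step.
`gcio` re-implements that analysis as a tested pipeline for
electrophysiologists and quantitative neuroscientists: from raw current-clamp
sweep bundles, through the bespoke gain statistics, to the two-population
inference — together with a ground-truthed synthetic cohort generator that
stands in for the unpublished recordings.

## The statistics at the core

For one cell and one sinusoid frequency `f` (Hz, from the protocol grid
5/10/20/40/60/80), let `n(A)` be the number of spikes fired during a 1 s
sinusoidal injection of peak amplitude `A` (50 pA grid), and let
`d_j = n(A_{j+1}) − n(A_j)` be the successive increments over the included
(non-lacking, non-saturated) part of the curve. Then

* **ASL** (average slope, the gain): `asl_f = mean(d) / √f`
* **VAR** (gain variability): `var_f = Var(d) / f` (sample variance)
* **offset**: `offset_f = A* / f^(1/4)` where `A*` is the smallest amplitude
  whose count strictly exceeds `f/2` (output rate above half the drive
  frequency).

Per-cell pooled values are arithmetic means of the defined per-frequency
values. High ASL marks large output change per 50 pA input step; high VAR
marks sensitivity to a narrow input band (one dominant jump in the curve).

Downstream, the per-cell pooled statistic is tested for bimodality
(histogram least-squares one- vs two-Gaussian fits summarized by an
extra-sum-of-squares F statistic, with the decision p-value from a
parametric-bootstrap-calibrated likelihood-ratio test), split by K-means
(k = 2; the higher-gain cluster is S), and related to cell age and input
resistance. Ward hierarchical clustering on the seven z-scored intrinsic
parameters (RMP, τ_M, C_m, R_in, AP threshold, peak dV/dt, maximal rate)
checks that the S/L identity is *not* recoverable from passive maturation
state.

Feature extraction follows fixed conventions: spikes are upward crossings of
20 mV/ms in the derivative of the 4 kHz zero-phase low-pass filtered trace
(peak dV/dt taken unfiltered); R_in is the mean steady-state response to
−10 pA steps after excluding sweeps with large spontaneous events; τ_M is the
mean of single-exponential fits 2–100 ms after step onset and offset; C_m is
transient charge over step amplitude from a −5 mV voltage-clamp step; cells
are excluded when the resting potential drifts > 4 mV or when
R_in < 90 MΩ (semilunar granule cells).

## Worked example

```r
library(gcio)

# the frozen arithmetic example: included counts [1,3,4,8,9] at 10 Hz
cv <- mask_io_curve(io_curve(10, seq(50, 450, 50), c(0, 0, 1, 3, 4, 8, 9, 9, 7)))
compute_io_statistics(cv)
#> asl_f = 0.6325, var_f = 0.200     (increments d = [2,1,4,1])

# a 120-cell synthetic cohort with retained S/L truth
co    <- generate_cohort(cohort_spec(n_cells = 120, seed = 7))
feats <- cohort_features(co)

compare_gaussians(feats$asl, seed = 7)
#> Gaussian comparison (n = 120, 12 bins)
#>   one:  mu 1.338, sigma 2.629 (SSE 1.309)
#>   two:  mu 1.471/2.355, sigma 0.287/0.198 (SSE 0.6485)
#>   extra-SS F = 2.04 (nominal p = 0.21); bootstrap LRT p = 0.008264 -> prefer two

km <- kmeans_two(feats$asl)
km
#> K-means (k = 2): S 2.361 +/- 0.140 (n = 66), L 1.594 +/- 0.150 (n = 54),
#> ANOVA p = 8.99e-47

ward <- ward_cluster_seven(feats, km$labels)
ward$agreement
#> accuracy 0.64, ARI 0.072   (intrinsic parameters do not predict S/L)

group_correlations(feats, km$labels)[c(1, 2, 9), ]
#>  stat        group   n     slope adjusted_r2  p_value
#>  asl         S      66 -1.34e-05    -0.0078   0.48     (gain independent of Rin)
#>  asl         L      54  1.55e-04     0.454    1.4e-08  (gain tracks Rin)
#>  offset_norm pooled 120 -9.55e-03    0.324    6.9e-12  (offset tracks Rin)
```

The comparison prefers two Gaussian components (bootstrap p = 0.008); the
K-means centers (2.36 / 1.59) recover the generating group means; within the
S group the gain is uncorrelated with input resistance while the L-group gain
and the offset (both groups) track it — the dependence structure the
generator encodes.

## One-command pipeline

```r
run_pipeline(list(seed = 20140724, cohort = list(n_cells = 120),
                  out_dir = "out"))
# writes features.csv, per_frequency.csv, age_probabilities.csv,
# report.json, exclusions.log — byte-identical across reruns of one seed
```

or from the shell (after install):

```sh
Rscript $(Rscript -e 'cat(system.file("cli/gcio.R", package="gcio"))') \
    all --config cfg.json --seed 20140724 --out out/
```

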
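# polfrap

Kinetic inference for RNA polymerase II strip-FRAP.

## The problem

In strip-FRAP a narrow strip spanning a nucleus expressing GFP-tagged
RPB1 (the largest subunit of Pol II) is photobleached with a single
high-power frame, and the recovery of in-strip fluorescence is followed at
0.4-s resolution for minutes. The curve mixes three kinetically distinct
pools: freely diffusing Pol II (recovers in seconds), promoter-bound Pol II
(initiating and promoter-proximally paused; chromatin residence under a
minute, shapes the curve below ~50 s), and elongating Pol II (residence
above 20 min on average, sets the late slope). Changes in the curve after
UV irradiation therefore report how transcription-blocking DNA damage
redistributes Pol II between these pools: an elongation block in cis
prolongs the elongating residence time, while the trans-acting degradation
of promoter-bound Pol II in the second hour after UV shrinks the
promoter-bound fraction and the total Pol II level.

Because a bounded three-state reaction–diffusion system has no usable
closed form, kinetics are inferred by simulation-based fitting: candidate
models are pushed through a particle-based Monte Carlo simulation of the
exact acquisition protocol and scored against the measured curve.

## The model

A `kinetic_model` is (f_free, f_prom, f_elong; t_prom, t_elong; D) — the
steady-state pool fractions (summing to 1), the mean chromatin residence
times of the two bound states, and the free diffusion coefficient. Both
bound states exchange with one free pool; unbinding rates are 1/t_prom and
1/t_elong (exponential dwell) and pseudo-first-order binding rates

    k_on,p = f_prom  / (f_free * t_prom)
    k_on,e = f_elong / (f_free * t_elong)

make the configured fractions the exact stationary distribution. Fits are
grid searches: every candidate model on a parameter grid is simulated with
fixed seeds and scored by the sum of squared RFI differences over
post-bleach frames; a fit is reported as the mean ± SD of each parameter
over the 20 best-fitting simulations, and conditions are compared as
percent changes of those means.

## Package tour

* `frap_trace()`, `background_correct()`, `normalize_prebleach()`,
  `average_curves()`, `prebleach_level_summary()` — preprocessing of raw
  per-cell traces: background correction, normalization of the pre-bleach
  mean (frames 10–20) to RFI = 100, per-condition averaging, and the
  pre-bleach intensity as a total-protein proxy.
* `simulate_frap()` with `kinetic_model()`, `geometry_config()`,
  `acquisition_config()`, `simulation_config()` — the Monte Carlo engine
  (ellipsoidal nucleus, immobile bound states, seeded and reproducible);
  `init_population()`, `step_particles()`, `bleach_ensemble()`,
  `readout_strip()` expose its primitives.
* `parameter_grid()`, `simulate_grid()`, `grid_fit()`, `select_best()`,
  `compare_conditions()`, `calibrate_bleach_depth()` — the grid-search
  fitting engine, with common-random-number and control-variate variance
  reduction (see the methods vignette).
* `condition_model()`, `generate_cells()`, `noise_spec()` — ground-truth
  models for the UV-damage scenario conditions and a noisy per-cell trace
  generator, so the whole chain is testable end to end.
* `run_scenario()` / `default_scenario()` — one-call orchestration:
  generate cohorts, preprocess, fit every condition on one shared grid,
  compare conditions, write curves/fits/figures/manifest.
* `analysis/01...04_*.R` — the same workflow as narrative scripts writing
  under `results/`.

## Worked example

```r
library(polfrap)

model <- condition_model("0 J")
model
#> Three-state kinetic model
#>   fractions: free 0.25 / promoter-bound 0.45 / elongating 0.3
#>   residence: t_prom 30 s, t_elong 1380 s (23 min, exponential dwell)
#>   D = 2 um^2/s, level_scale = 1

sim <- simulation_config(n_particles = 10000, dt = 0.02)
curve <- simulate_frap(model, sim, seed = 1)
curve
#> Simulated strip-FRAP curve: 626 frames, 10000 particles, seed 1
#>   first post-bleach RFI 14.9, final RFI 75.0
```

The drop to ~15 RFI reflects the 0.85 bleach depth; the fast recovery
within the first minute is the free plus promoter-bound exchange, and the
slow tail toward ~75 at 4 min is elongating Pol II, most of which stays
bound for the whole recording.

The full synthetic UV scenario (three conditions, 10 cells each, shared
fitting grid) runs with:

```r
res <- run_scenario(default_scenario(seed = 1), out_dir = "results/run")
res$deltas[res$deltas$parameter %in% c("t_elong", "f_prom"), ]
```

which reports the recovered percent change of the elongating residence
time in the first hour after 4 J/m² UV (+25% generated), the recovered
loss of promoter-bound fraction in the second hour (−75% generated), and
the pre-bleach protein-level proxy (0.75 generated).

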
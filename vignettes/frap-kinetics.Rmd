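---
title: "Kinetic inference from Pol II strip-FRAP: model, simulator and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic inference from Pol II strip-FRAP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the question

In strip-FRAP a narrow strip spanning the nucleus is photobleached with a
single high-power frame and the return of fluorescence into the strip is
followed over minutes. For GFP-tagged RPB1 (the largest subunit of RNA
polymerase II), recovery mixes two processes with very different
timescales: diffusion of unengaged Pol II into the strip within seconds,
and the slow exchange of chromatin-engaged Pol II. Promoter-bound Pol II
(initiating plus promoter-proximally paused) resides on chromatin for under
a minute and shapes the early recovery (&lt; 50 s); elongating Pol II
resides for more than 20 min on average and dominates the slope of the late
curve (&gt; 100 s). A recovery curve therefore carries quantitative
information about how the Pol II pool partitions over free, promoter-bound
and elongating states and how long the bound states last — exactly the
quantities that change when UV damage blocks elongation in cis or triggers
the degradation of promoter-bound Pol II in trans.

Because the recovery of a reaction–diffusion system in a bounded,
non-trivial geometry has no usable closed form at these parameter ranges,
the package infers kinetics by simulation-based fitting: candidate kinetic
models are simulated through the exact acquisition protocol and scored
against the measured curve.

## The three-state kinetic model

A `kinetic_model` holds:

* `f_free`, `f_prom`, `f_elong` — steady-state fractions of the pool
  (summing to 1);
* `t_prom`, `t_elong` — mean chromatin residence times (s) of the
  promoter-bound and elongating states;
* `D` — free diffusion coefficient (µm²/s), default 2.0 for GFP-RPB1-sized
  complexes;
* `level_scale` — a total-abundance multiplier used only when converting
  relative fluorescence into raw intensity units (protein-level changes,
  e.g. degradation, move it below 1).

Both bound states exchange with one free pool. Unbinding is memoryless with
rates `1/t_prom` and `1/t_elong`; binding is pseudo-first-order with rates

```
k_on,p = f_prom  / (f_free * t_prom)
k_on,e = f_elong / (f_free * t_elong)
```

chosen so the configured fractions are the exact stationary distribution
(detailed balance with exponential dwells is the minimal scheme consistent
with specifying fractions and mean residence times only). Because
productive elongation is processive rather than memoryless, a
fixed-duration elongating dwell is available via
`elongating_dwell = "fixed"`; the exponential default was retained because
the late slope of a strip-FRAP curve constrains the mean dwell far more
strongly than the dwell-time shape at these acquisition lengths.

## The Monte Carlo engine

Particles move inside a 3-D ellipsoidal nucleus, by default with semi-axes
10 × 5 × 2.5 µm (a flat adherent fibroblast nucleus). The strip is an
axis-aligned slab through the centre, 1.5 µm wide along the long in-plane
axis and spanning the nucleus in the other two; only a physical mapping of
the instrument's 512 × 32-pixel strip is needed, and both the ellipsoid
and the strip width are configurable.

Each acquisition frame (0.4 s) is split into diffusion substeps
(`dt = 0.02` s by default, giving 20 substeps per frame). Per substep:

* free particles take isotropic Gaussian steps with per-axis SD
  `sqrt(2 D dt)` (~0.28 µm at defaults, comfortably below the strip
  width); a step that would exit the nucleus is redrawn (rejection),
  which preserves detailed balance for small steps;
* state transitions occur with per-substep probability
  `1 − exp(−rate·dt)` (&lt; 0.001 at default rates, so first-order
  discretization error is negligible). Internally each transition's
  waiting time is drawn as a whole number of substeps with exactly that
  per-substep law (a continuous exponential deviate discretized by
  `ceil`), which is distributionally identical to testing every substep
  but avoids one uniform draw per particle per substep, and makes the two
  binding channels compete at their exact rate ratio;
* a bound particle is immobile and rebinds where it unbound; binding
  sites are assumed uniformly distributed, so a free particle can bind
  anywhere.

The protocol runs 25 pre-bleach frames, one bleach frame in which every
particle inside the strip is darkened with probability `bleach_depth`
(default 0.85), and recovery frames for 4 min. The readout is the
fluorescence of the particles inside the strip; the curve is normalized so
that its mean over the pre-bleach reference window is 100, matching the
preprocessing of measured data. Equal seeds give bitwise-identical curves;
the seed is recorded in every output.

### Random-number layout and variance reduction

Grid-search fitting compares kinetic models whose expected curves differ
by well under 1 RFI unit in the late recovery, so the engine is built to
make simulated curves as accurate per particle as an unbiased estimator
allows. All per-particle and per-event marginal distributions are exactly
the nominal ones; the measures below only remove estimator variance:

* **Common random numbers.** Diffusion displacements are a pure
  counter-based function of (seed, particle, substep, attempt), drawn as
  the sign-randomized sum of two entries of a fixed table of
  variance-normalized normal triples; each particle's sequential stream is
  reserved for kinetic decisions, whose draw sequence is invariant across
  parameter values. Two simulations sharing a seed therefore share the
  trajectories of every particle not genuinely affected by a parameter
  change: the curve *difference* between two candidate models is an order
  of magnitude less noisy than either curve alone.
* **Stratified initialization.** State counts are deterministic
  (blockwise assignment, stable under small fraction changes); x positions
  within each state block follow the stratified inverse CDF of the
  ellipsoid's x marginal; initial residual dwell times of the bound blocks
  are Latin-hypercube stratified with a seeded permutation so that dwell
  strata are independent of position strata. This pins initial state
  shares, initial in-strip bound occupancy, and the number of
  initially-bound particles releasing within any horizon to their
  expectations.
* **Expectation bleach.** Instead of a Bernoulli lottery, each in-strip
  particle's fluorescence weight is multiplied by `1 − bleach_depth` —
  the Rao-Blackwellized expectation over the lottery — so the curve
  carries no bleach-assignment noise. (The exported `bleach_ensemble()`
  operation retains the per-particle Bernoulli semantics for ensemble
  work.)

The residual simulation noise after all of this is reaction–diffusion
transport noise — which particles happen to carry the bleach deficit
where — and it motivates the control-variate estimator used by the fit
(next section).

The engine is validated against independent physics in the test suite: the
Einstein relation for free diffusion, binomial bounds on initialization and
bleaching, stationarity of the state occupancies, particle/fluorophore
conservation, and — for a diffusion-only model in a nucleus much wider than
the strip — the closed-form 1-D solution in which the bleach deficit is a
top-hat evolving under the heat kernel (error-function profile integrated
over the strip), with a maximum discrepancy under 3 RFI units at 2 × 10⁵
particles.

## Preprocessing conventions

Raw per-cell traces carry in-strip and out-of-strip (background) intensity
per frame. The chain is:

1. `background_correct()` — subtract the background framewise; negative
   differences are clipped to 0 (behaviour for that edge case is a package
   convention; clipping keeps RFI physical).
2. `normalize_prebleach()` — divide by the mean corrected intensity over
   pre-bleach frames 10–20 and multiply by 100. Frame indices are 0-based
   over the pre-bleach block (R indices 11–21), a documented choice since
   the convention of the protocol description is ambiguous; the window is
   configurable. The window mean is the pre-bleach fluorescence intensity,
   kept as a per-cell proxy for total Pol II protein level
   (`prebleach_level_summary()` reports it per condition, optionally
   relative to a reference condition).
3. Times are re-zeroed at the bleach frame, so pre-bleach frames carry
   negative times and measured and simulated curves share one axis.
4. `average_curves()` — pointwise mean and sample SD across the 8–10 cells
   of a condition; unequal-length curves are truncated to the shortest
   with a warning (recordings stop between 3 and 4 min).

Normalization is idempotent and invariant to any positive acquisition gain
applied to both channels; both properties are enforced by tests.

## Grid-search fitting

The paper-level question — how fractions and residence times differ between
conditions — is answered by scoring a grid of candidate models:

* `parameter_grid()` crosses candidate values of `f_prom`, `f_elong`,
  `t_prom`, `t_elong` (the free fraction is implied); each grid point gets
  `n_replicates` simulation seeds assigned at construction — shared across
  grid points (common random numbers) — so reordering the grid changes
  nothing.
* `simulate_grid()` can estimate each grid curve with a control variate:
  one high-particle reference simulation per (`f_prom`, `f_elong`) family
  at the median `t_prom` and an *off-grid* mean `t_elong`, plus the
  common-random-number difference between small paired simulations of the
  grid point and the reference, averaged over `cv_seeds` seeds. The
  reference's Monte Carlo error is identical for every residence-time
  combination in its family, so it cannot distort the residence-time
  ranking; the off-grid `t_elong` reference guarantees that every
  candidate residence time carries a comparable (small) difference-noise
  floor — a reference on a grid value would make that point's curve exact
  and attract the fit to it. All families share one reference seed, so
  reference errors are themselves coupled across fraction pairs and
  largely drop out of between-condition comparisons.
* `score_curve()` is the unweighted sum of squared RFI differences over
  post-bleach frames (the bleach frame included). Pre-bleach frames are
  excluded because both curves are pinned to 100 there. SSE is the minimal
  objective for a curve-matching fit and is isolated behind this one
  function so an alternative (e.g. variance-weighted) objective can be
  substituted.
* `grid_fit()` returns the complete scored list sorted ascending; ties at
  the cutoff are broken by grid enumeration order (documented, stable).
* `select_best()` reports the mean ± SD of every parameter over the
  `n_best = 20` lowest-scoring simulations — the standard summary for this
  kind of simulation-based FRAP fit. With replicate seeds enabled, the best
  20 may contain one grid point more than once; with one seed per point
  they are 20 distinct models. Replicates are not only jitter reduction:
  when the fractions are well identified, the winning fraction pair
  contributes only `6 × 3 = 18` residence-time combinations, so with a
  single seed per point the best 20 necessarily includes *every*
  `t_elong` value and its mean collapses to the grid average regardless
  of the data. At least two entries per grid point are required for the
  20-best summary to express a peaked residence-time estimate; the
  package's own analyses use two.
* `compare_conditions()` reports `100 (b − a)/a` per parameter mean, with a
  zero denominator flagged rather than raised.

Two quantities are deliberately not fitted: the diffusion coefficient `D`
(fixed at 2.0 µm²/s; the early seconds of the curve constrain it poorly
once bound fractions are free parameters) and `bleach_depth`, which is
calibrated per dataset from the first post-bleach RFI of the reference
condition (`calibrate_bleach_depth()`: immediately after a single-frame
bleach the expected in-strip RFI is `100 (1 − depth)`), then held fixed
across the grid. Replicate seeds (`n_replicates = 2` in the package's own
analyses) reduce the Monte Carlo jitter of scores near the optimum at
linear cost.

## The synthetic-data generator

`condition_model()` fixes one ground-truth model per experimental
condition of the UV scenario:

| condition      | f_free | f_prom | f_elong | t_prom | t_elong  | level |
|----------------|--------|--------|---------|--------|----------|-------|
| `0 J`          | 0.25   | 0.45   | 0.30    | 30 s   | 23 min   | 1.00  |
| `4 J 0-1 h`    | 0.20   | 0.45   | 0.35    | 30 s   | 28.75 min| 1.00  |
| `4 J 1-2 h`    | 0.5375 | 0.1125 | 0.35    | 30 s   | 28.75 min| 0.75  |
| `4 J 20-21 h`  | 0.25   | 0.45   | 0.30    | 30 s   | 23 min   | 1.00  |

The *relative* changes are the substance being emulated: the first hour
after UV prolongs the elongating residence by 25 % (stalling at
transcription-blocking lesions slows elongation in cis) and slightly
enlarges the elongating fraction; the second hour depletes the
promoter-bound fraction by 75 % and lowers total protein to 0.75 of
baseline (degradation of promoter-bound Pol II in trans); by 20–21 h both
effects have resolved. The absolute baseline values are package
conventions, chosen once to satisfy the published qualitative bounds
(promoter-bound residence under a minute; elongating residence above
20 min; a roughly half-engaged pool, as expected for a largely
chromatin-associated polymerase) — they are not measured values, and the
tests assert only the bounds and the relative changes. A `16 J 0-1 h`
variant carries the same full 25 % in-cis effect with no extra in-trans
loss, reflecting the observation that the trans response does not scale
with damage load.

`generate_cells()` turns a model into raw per-cell traces: each cell is an
independent Monte Carlo run (distinct seed), scaled by a mean-centred
lognormal per-cell expression level (`cell_scale_sd = 0.1`) times
`level_scale` and a base level of 1000 a.u., plus a constant background
(10 % of the cohort's mean pre-bleach signal) and per-frame Gaussian noise
(`frame_noise_sd = 2` RFI units). These defaults give per-cell scatter
visually comparable to published GFP-RPB1 strip-FRAP panels and are all
configurable. With all noise at zero the chain inverts exactly:
generate → background-correct → normalize reproduces the simulated RFI to
1e-9, a property the tests enforce.

What the generator does **not** emulate — and what recovery tests on it
therefore cannot show about real data: photophysics (blinking, reversible
bleaching), anomalous or state-dependent diffusion, spatially
heterogeneous binding-site density, cell-to-cell variability of the
kinetic parameters themselves (only expression level varies), drift or
segmentation error in the intensity extraction, and local-damage
(micropore) geometries. Passing recovery tests demonstrate that the
fitting chain is unbiased and correctly seeded under the stated model, not
that the model is complete for any particular microscope.

## Problem sizes and numerical choices

The package's own analyses (the `analysis/` scripts, the acceptance script
and the end-to-end tests) use: 10 cells per condition, simulated at
5 × 10⁴ particles so that their residual counting noise sits below the
2-RFI designed measurement noise that is meant to dominate; the fitting
grid `f_prom ∈ {0.1125, 0.28, 0.45}`, `f_elong ∈ {0.25, 0.30, 0.35}`,
`t_prom ∈ {15, 30, 60}` s, `t_elong ∈ {18, 20, 23, 25, 28.75, 32}` min —
162 points chosen to bracket all condition models with the truth on
interior grid lines; hybrid curve estimates with one 7 × 10⁴-particle
Monte Carlo anchor per fraction pair and replicate seed (eight replicate
seeds) plus deterministic expected-curve differences; and 10 substeps per
frame (`dt = 0.04` s — coarser than the package default, which is
harmless here because the generator and the fit share the lattice, so
discretization effects cancel in the comparison). At 10⁴ particles
roughly 1100 sit in the strip, giving per-frame counting noise of ~3 RFI
units on a raw simulated curve — orders of magnitude above the ≲1-RFI
late-curve differences that separate neighbouring residence times, which
is why the fit rests on the hybrid estimator rather than on raw
simulations per grid entry. The 20-best averaging then aggregates the
residence-time rankings obtained under the eight anchor realizations.
Even so, the recovered per-condition elongating-residence means retain
roughly one grid step of uncertainty, and the between-condition percent
change of the elongating residence scatters by several percentage points
around the generated +25% across seeds; the promoter-bound fraction
change, carried by a far larger curve signal, is recovered essentially
exactly. Unit tests run reduced versions (shorter recovery, fewer
particles, scaled-down residence times) of every property.

Other numerical conventions: transitions and diffusion share the substep
lattice; `frame_interval` must be an integer multiple of `dt`; rejection
resampling caps at 100 attempts per step (beyond that the particle stays
put — unreachable at sane `D·dt`); a degenerate reference window (zero
pre-bleach signal) is an error, not a NaN; fraction vectors must sum to 1
within 1e-9.

## Limitations

* Inference quality is grid-limited: the 20-best mean shrinks toward the
  local grid neighbourhood, so percent changes between conditions are
  recovered more faithfully than absolute values — which is also why
  conclusions are phrased as condition deltas.
* The SSE objective weights all post-bleach frames equally; with 600
  recovery frames the late curve dominates residence-time inference, and
  very early binding kinetics (sub-frame) are invisible.
* `D` and the bleach profile are inputs, not outputs; a miscalibrated
  bleach depth biases the apparent free fraction.
* Elongating dwell shape (exponential vs fixed) is not identifiable from
  these curves; both options are provided but only the mean dwell should
  be interpreted.
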
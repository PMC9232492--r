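# Shared fixtures: small acquisition/simulation settings for fast tests,
# the closed-form diffusion oracle, and a cached end-to-end scenario run.

tiny_acquisition <- function(recovery = 20, bleach_depth = 0.85) {
  acquisition_config(frame_interval = 0.4, n_prebleach = 10,
                     recovery_duration = recovery,
                     bleach_depth = bleach_depth,
                     reference_frames = c(3, 8))
}

tiny_sim <- function(n = 2000, recovery = 20, bleach_depth = 0.85,
                     dt = 0.02) {
  simulation_config(n_particles = n, dt = dt,
                    acquisition = tiny_acquisition(recovery, bleach_depth))
}

# Closed-form in-strip RFI for pure diffusion after bleaching a slab of
# width w to depth bd, on an effectively unbounded x axis: the bleach
# deficit is a top-hat evolving under the 1D heat kernel; integrating the
# error-function profile over the strip gives the recovery.
theory_strip_rfi <- function(t, D, w, bd) {
  if (t <= 0) return(100 * (1 - bd))
  s4 <- sqrt(4 * D * t)
  erf <- function(q) 2 * pnorm(q * sqrt(2)) - 1
  integrand <- function(x) 0.5 * (erf((w / 2 - x) / s4) + erf((w / 2 + x) / s4))
  100 * (1 - bd / w *
           integrate(integrand, -w / 2, w / 2, rel.tol = 1e-9)$value)
}

# Wrap a simulated curve as a single-cell condition mean so it can be used
# as a fitting target.
as_mean_curve <- function(sim_curve, condition = "target") {
  structure(
    list(condition = condition, times = sim_curve$times,
         rfi_mean = sim_curve$rfi, rfi_sd = rep(0, length(sim_curve$rfi)),
         n_cells = 1L),
    class = "frap_mean_curve"
  )
}

# The full desk-scale scenario (three UV conditions, 10 cells each,
# 10^4-particle simulations, the default bracketing grid) is expensive, so
# it runs once per test session and is shared by the acceptance checks.
.scenario_cache <- new.env(parent = emptyenv())

acceptance_scenario <- function() {
  if (is.null(.scenario_cache$res)) {
    .scenario_cache$res <- run_scenario(default_scenario(seed = 101L),
                                        out_dir = NULL, quiet = TRUE)
  }
  .scenario_cache$res
}
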
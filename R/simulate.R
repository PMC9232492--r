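#' Initialize a particle ensemble at kinetic steady state
#'
#' Draws `n_particles` positions uniformly inside the nuclear ellipsoid and
#' assigns each particle a kinetic state from the model's steady-state
#' fractions. All particles start fluorescent.
#'
#' @param model A [kinetic_model()].
#' @param sim A [simulation_config()].
#' @param seed Integer seed; the same seed reproduces the ensemble exactly.
#'
#' @return An object of class `frap_ensemble`: a list with `positions`
#'   (n x 3 matrix, um), `state` (integer; 0 free, 1 promoter-bound,
#'   2 elongating), `fluorescent` (logical) and `geometry`.
#' @export
init_population <- function(model, sim, seed = 1L) {
  stopifnot(inherits(model, "kinetic_model"),
            inherits(sim, "simulation_config"))
  g <- sim$geometry
  out <- .mc_init_cpp(sim$n_particles, model$f_free, model$f_prom,
                      model$f_elong, g$semi_axes[1], g$semi_axes[2],
                      g$semi_axes[3], g$strip_width, as.double(seed))
  structure(
    list(positions = out$positions, state = out$state,
         fluorescent = rep(TRUE, sim$n_particles), geometry = g),
    class = "frap_ensemble"
  )
}

#' Advance an ensemble by diffusion/exchange substeps
#'
#' Free particles take isotropic Gaussian steps with per-axis SD
#' `sqrt(2 * D * dt)`, reflected at the nuclear envelope by rejection
#' resampling; bound particles are immobile. State transitions are evaluated
#' each substep with probability `1 - exp(-rate * dt)` (exponential dwell).
#'
#' @param ensemble A `frap_ensemble` from [init_population()].
#' @param model A [kinetic_model()].
#' @param dt Substep duration in seconds (> 0).
#' @param n_steps Number of substeps to take.
#' @param seed Integer seed for this block of substeps.
#'
#' @return The advanced `frap_ensemble`.
#' @export
step_particles <- function(ensemble, model, dt, n_steps = 1L, seed = 1L) {
  stopifnot(inherits(ensemble, "frap_ensemble"),
            inherits(model, "kinetic_model"), dt > 0, n_steps >= 1)
  g <- ensemble$geometry
  out <- .mc_step_cpp(ensemble$positions, ensemble$state, model$f_free,
                      model$f_prom, model$f_elong, model$t_prom,
                      model$t_elong, model$D, g$semi_axes[1], g$semi_axes[2],
                      g$semi_axes[3], g$strip_width, dt,
                      as.integer(n_steps), as.double(seed))
  ensemble$positions <- out$positions
  ensemble$state <- out$state
  ensemble
}

#' Apply a bleach pulse to the strip
#'
#' Each fluorescent particle currently inside the strip is darkened with
#' probability `bleach_depth`; particles outside the strip are unaffected.
#'
#' @param ensemble A `frap_ensemble`.
#' @param bleach_depth Darkening probability in (0, 1].
#' @param seed Integer seed for the Bernoulli draws.
#'
#' @return The ensemble with its `fluorescent` flags updated.
#' @export
bleach_ensemble <- function(ensemble, bleach_depth, seed = 1L) {
  stopifnot(inherits(ensemble, "frap_ensemble"),
            bleach_depth >= 0, bleach_depth <= 1)
  in_strip <- abs(ensemble$positions[, 1]) <= ensemble$geometry$strip_width / 2
  hit <- ensemble$fluorescent & in_strip
  if (any(hit) && bleach_depth > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    dark <- runif(sum(hit)) < bleach_depth
    ensemble$fluorescent[which(hit)[dark]] <- FALSE
  }
  ensemble
}

#' Strip fluorescence readout
#'
#' Counts the fluorescent particles whose position lies inside the strip —
#' the simulated analogue of the in-strip fluorescence intensity.
#'
#' @param ensemble A `frap_ensemble`.
#' @return Integer count.
#' @export
readout_strip <- function(ensemble) {
  stopifnot(inherits(ensemble, "frap_ensemble"))
  in_strip <- abs(ensemble$positions[, 1]) <= ensemble$geometry$strip_width / 2
  sum(ensemble$fluorescent & in_strip)
}

#' Simulate a strip-FRAP experiment
#'
#' Runs the full acquisition protocol: pre-bleach frames, a single-frame
#' bleach pulse, then recovery frames, with diffusion and state exchange
#' substepped at `sim$dt` between frames. The in-strip fluorescent-particle
#' count per frame is normalized so that its mean over the pre-bleach
#' reference window equals 100.
#'
#' @param model A [kinetic_model()].
#' @param sim A [simulation_config()].
#' @param seed Integer seed; identical seeds give bitwise-identical curves.
#'
#' @return An object of class `frap_sim_curve`: list with `times` (s,
#'   zeroed at the bleach frame), `rfi`, raw `counts`, `total_fluorescent`
#'   per frame, `n_bleached`, the `model`, `sim` and `seed`.
#' @examples
#' m <- kinetic_model(1, 0, 0, t_prom = 1, t_elong = 1, D = 5)
#' s <- simulation_config(n_particles = 500,
#'                        acquisition = acquisition_config(recovery_duration = 4))
#' sim <- simulate_frap(m, s, seed = 7)
#' @export
simulate_frap <- function(model, sim, seed = 1L) {
  stopifnot(inherits(model, "kinetic_model"),
            inherits(sim, "simulation_config"))
  acq <- sim$acquisition
  g <- sim$geometry
  n_sub <- as.integer(round(acq$frame_interval / sim$dt))
  n_rec <- n_recovery_frames(acq)
  out <- .mc_frap_cpp(sim$n_particles, model$f_free, model$f_prom,
                      model$f_elong, model$t_prom, model$t_elong, model$D,
                      g$semi_axes[1], g$semi_axes[2], g$semi_axes[3],
                      g$strip_width, acq$frame_interval, acq$n_prebleach,
                      n_rec, acq$bleach_depth, sim$dt, n_sub,
                      identical(model$elongating_dwell, "fixed"),
                      as.double(seed))
  counts <- as.numeric(out$counts)
  ref <- mean(counts[reference_indices(acq)])
  if (ref <= 0)
    stop("degenerate simulation: no fluorescence in the reference window",
         call. = FALSE)
  structure(
    list(times = frame_times(acq), rfi = 100 * counts / ref, counts = counts,
         total_fluorescent = as.numeric(out$total_fluorescent),
         n_bleached = out$n_bleached, model = model, sim = sim,
         seed = as.integer(seed)),
    class = "frap_sim_curve"
  )
}

#' Deterministic expected strip-FRAP curve
#'
#' Computes the model's expected recovery curve (no Monte Carlo noise) by
#' solving the reaction-diffusion equations of the three-state model on
#' the x marginal of the ellipsoidal nucleus: the cross-section area
#' `A(x) = 1 - (x/a)^2` weights a 1D system for the bright line densities
#' of the free, promoter-bound and elongating pools, advanced by
#' Crank-Nicolson on the acquisition substep. The strip readout depends on
#' x only, so no other coordinate is needed. The x marginal of a 3D
#' reflected diffusion is not exactly Markov, so this expectation carries
#' a small closure error; the grid fit therefore uses it only for
#' *differences* between nearby models, anchored at Monte Carlo reference
#' simulations (see [simulate_grid()]), where the closure error cancels to
#' second order.
#'
#' @param model A [kinetic_model()] with exponential elongating dwell.
#' @param sim A [simulation_config()] (its particle count is ignored).
#' @param K Number of spatial cells across the nucleus.
#' @return A `frap_sim_curve` with `seed = NA` (deterministic).
#' @export
expected_frap_curve <- function(model, sim, K = 301L) {
  stopifnot(inherits(model, "kinetic_model"),
            inherits(sim, "simulation_config"))
  if (identical(model$elongating_dwell, "fixed"))
    stop("expected_frap_curve supports the exponential dwell only",
         call. = FALSE)
  acq <- sim$acquisition
  g <- sim$geometry
  n_sub <- as.integer(round(acq$frame_interval / sim$dt))
  n_rec <- n_recovery_frames(acq)
  rfi <- .pde_frap_cpp(model$f_free, model$f_prom, model$f_elong,
                       model$t_prom, model$t_elong, model$D,
                       g$semi_axes[1], g$strip_width, acq$frame_interval,
                       acq$n_prebleach, n_rec, acq$bleach_depth, sim$dt,
                       n_sub, as.integer(K))
  structure(
    list(times = frame_times(acq), rfi = as.numeric(rfi), counts = NULL,
         total_fluorescent = NULL, n_bleached = NA_real_, model = model,
         sim = sim, seed = NA_integer_),
    class = "frap_sim_curve"
  )
}

#' @export
print.frap_sim_curve <- function(x, ...) {
  post <- x$rfi[x$times >= 0]
  cat(sprintf(
    "Simulated strip-FRAP curve: %d frames, %d particles, seed %d\n",
    length(x$times), x$sim$n_particles, x$seed))
  cat(sprintf("  first post-bleach RFI %.1f, final RFI %.1f\n",
              post[1], post[length(post)]))
  invisible(x)
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
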
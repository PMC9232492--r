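#' Three-state kinetic model of nuclear Pol II
#'
#' Describes the steady-state partitioning of a nuclear protein over one
#' freely diffusing and two immobile chromatin-bound states (promoter-bound
#' and elongating), together with the mean residence time of each bound
#' state, the free diffusion coefficient, and a total-abundance multiplier
#' used when converting relative fluorescence to raw intensity units.
#'
#' @param f_free,f_prom,f_elong State fractions (dimensionless); must sum
#'   to 1 within `1e-9` and each lie in `[0, 1]`.
#' @param t_prom Mean promoter-bound residence time in seconds (> 0).
#' @param t_elong Mean elongating residence time in seconds (> 0).
#' @param D Free diffusion coefficient in um^2/s (> 0).
#' @param level_scale Dimensionless total-protein-level multiplier (> 0);
#'   1 is the unperturbed level.
#' @param elongating_dwell Dwell-time law of the elongating state:
#'   `"exponential"` (memoryless, the default) or `"fixed"` (deterministic
#'   dwell of exactly `t_elong`, a processive-elongation alternative).
#'
#' @return An object of class `kinetic_model`.
#' @examples
#' kinetic_model(0.25, 0.45, 0.30, t_prom = 30, t_elong = 23 * 60)
#' @export
kinetic_model <- function(f_free, f_prom, f_elong, t_prom, t_elong,
                          D = 2.0, level_scale = 1.0,
                          elongating_dwell = c("exponential", "fixed")) {
  elongating_dwell <- match.arg(elongating_dwell)
  fr <- c(f_free = f_free, f_prom = f_prom, f_elong = f_elong)
  if (any(!is.finite(fr)) || any(fr < -1e-12) || any(fr > 1 + 1e-12))
    stop("state fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("state fractions must sum to 1 (got ", format(sum(fr), digits = 12),
         ")", call. = FALSE)
  if (!is.finite(t_prom) || t_prom <= 0) stop("t_prom must be > 0", call. = FALSE)
  if (!is.finite(t_elong) || t_elong <= 0) stop("t_elong must be > 0", call. = FALSE)
  if (!is.finite(D) || D <= 0) stop("D must be > 0", call. = FALSE)
  if (!is.finite(level_scale) || level_scale <= 0)
    stop("level_scale must be > 0", call. = FALSE)
  structure(
    list(f_free = f_free, f_prom = f_prom, f_elong = f_elong,
         t_prom = t_prom, t_elong = t_elong, D = D,
         level_scale = level_scale, elongating_dwell = elongating_dwell),
    class = "kinetic_model"
  )
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Three-state kinetic model\n")
  cat(sprintf("  fractions: free %.4g / promoter-bound %.4g / elongating %.4g\n",
              x$f_free, x$f_prom, x$f_elong))
  cat(sprintf("  residence: t_prom %.4g s, t_elong %.4g s (%.3g min, %s dwell)\n",
              x$t_prom, x$t_elong, x$t_elong / 60, x$elongating_dwell))
  cat(sprintf("  D = %.3g um^2/s, level_scale = %.3g\n", x$D, x$level_scale))
  invisible(x)
}

#' Acquisition protocol for strip-FRAP
#'
#' Defaults reproduce the confocal strip-FRAP protocol used for GFP-RPB1:
#' one frame every 0.4 s, 25 pre-bleach frames, a single-frame bleach pulse,
#' and 4 min of recovery. The pre-bleach reference window used to define
#' RFI = 100 is frames 10-20 (0-based, inclusive) of the pre-bleach block.
#'
#' @param frame_interval Seconds between frames (> 0).
#' @param n_prebleach Number of pre-bleach frames (>= 1).
#' @param recovery_duration Seconds of post-bleach recovery imaging
#'   (>= `frame_interval`).
#' @param bleach_depth Probability in (0, 1] that a fluorophore inside the
#'   strip is darkened by the bleach pulse.
#' @param reference_frames Length-2 integer vector, first and last 0-based
#'   pre-bleach frame of the normalization window (inclusive).
#'
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_interval = 0.4, n_prebleach = 25,
                               recovery_duration = 240, bleach_depth = 0.85,
                               reference_frames = c(10, 20)) {
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  if (n_prebleach < 1) stop("n_prebleach must be >= 1", call. = FALSE)
  if (recovery_duration < frame_interval)
    stop("recovery_duration must be >= frame_interval", call. = FALSE)
  if (bleach_depth <= 0 || bleach_depth > 1)
    stop("bleach_depth must be in (0, 1]", call. = FALSE)
  reference_frames <- as.integer(round(reference_frames))
  if (length(reference_frames) != 2 || reference_frames[1] > reference_frames[2] ||
      reference_frames[1] < 0 || reference_frames[2] >= n_prebleach)
    stop("reference_frames must be within the pre-bleach block", call. = FALSE)
  structure(
    list(frame_interval = frame_interval, n_prebleach = as.integer(n_prebleach),
         recovery_duration = recovery_duration, bleach_depth = bleach_depth,
         reference_frames = reference_frames),
    class = "acquisition_config"
  )
}

#' Nuclear and bleach-strip geometry
#'
#' The nucleus is a 3D ellipsoid; the bleached strip is an axis-aligned slab
#' through the nucleus centre, of the given width along the long in-plane
#' axis (x) and spanning the nucleus in y and z. Defaults describe a flat
#' fibroblast nucleus (semi-axes 10 x 5 x 2.5 um) with a 1.5 um strip.
#'
#' @param semi_axes Length-3 numeric, ellipsoid semi-axes in um (all > 0).
#' @param strip_width Strip width in um; must be smaller than the nucleus
#'   diameter along x.
#'
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(semi_axes = c(10, 5, 2.5), strip_width = 1.5) {
  if (length(semi_axes) != 3 || any(semi_axes <= 0))
    stop("semi_axes must be three positive lengths", call. = FALSE)
  if (strip_width <= 0 || strip_width >= 2 * semi_axes[1])
    stop("strip_width must be positive and smaller than the nucleus diameter",
         call. = FALSE)
  structure(list(semi_axes = as.numeric(semi_axes),
                 strip_width = strip_width),
            class = "geometry_config")
}

#' Monte Carlo simulation settings
#'
#' @param n_particles Number of simulated molecules (>= 100).
#' @param dt Diffusion substep in seconds; `frame_interval` must be an
#'   integer multiple of `dt` (within `1e-9`). The default 0.02 s gives 20
#'   substeps per frame, with an RMS step of ~0.28 um at D = 2 um^2/s,
#'   well below the default strip width.
#' @param geometry A [geometry_config()].
#' @param acquisition An [acquisition_config()].
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_particles = 10000, dt = 0.02,
                              geometry = geometry_config(),
                              acquisition = acquisition_config()) {
  if (n_particles < 100) stop("n_particles must be >= 100", call. = FALSE)
  if (dt <= 0 || dt > acquisition$frame_interval)
    stop("dt must be in (0, frame_interval]", call. = FALSE)
  n_sub <- acquisition$frame_interval / dt
  if (abs(n_sub - round(n_sub)) > 1e-9)
    stop("frame_interval must be an integer multiple of dt", call. = FALSE)
  stopifnot(inherits(geometry, "geometry_config"),
            inherits(acquisition, "acquisition_config"))
  structure(
    list(n_particles = as.integer(n_particles), dt = dt,
         geometry = geometry, acquisition = acquisition),
    class = "simulation_config"
  )
}

# Frame times for an acquisition: pre-bleach frames carry negative times,
# the bleach frame sits at t = 0, recovery frames follow at the frame
# interval.
frame_times <- function(acquisition) {
  P <- acquisition$n_prebleach
  R <- n_recovery_frames(acquisition)
  dt <- acquisition$frame_interval
  c((seq_len(P) - P - 1) * dt, 0, seq_len(R) * dt)
}

n_recovery_frames <- function(acquisition) {
  as.integer(round(acquisition$recovery_duration / acquisition$frame_interval))
}

# 1-based indices of the pre-bleach reference window in a full frame vector.
reference_indices <- function(acquisition) {
  (acquisition$reference_frames[1]:acquisition$reference_frames[2]) + 1L
}
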
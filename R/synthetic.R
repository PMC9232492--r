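#' Ground-truth kinetic model for a UV-damage scenario condition
#'
#' Returns the default three-state model emulating GFP-RPB1 kinetics under
#' each experimental condition of the UV-damage scenario:
#'
#' * `"0 J"` — unperturbed baseline: 25% free, 45% promoter-bound
#'   (residence 30 s), 30% elongating (residence 23 min), level 1.0. The
#'   exact values are package conventions chosen to satisfy the
#'   field-established bounds that promoter-bound Pol II resides on
#'   chromatin for under a minute while elongating Pol II resides for over
#'   20 min on average.
#' * `"4 J 0-1 h"` — the in-cis elongation block in the first hour after
#'   UV: elongating residence prolonged by 25% and the elongating fraction
#'   up 0.05 (taken from the free pool); total level unchanged.
#' * `"4 J 1-2 h"` — the in-trans response in the second hour: the
#'   promoter-bound fraction reduced by 75% (the released share returns to
#'   the free pool) and the total protein level scaled to 0.75.
#' * `"4 J 20-21 h"` — recovery: back to baseline.
#' * `"16 J 0-1 h"` — high-dose variant: the same full 25% in-cis
#'   prolongation, no additional in-trans loss (the trans effect does not
#'   scale with damage load).
#'
#' @param label Condition label (en dashes and extra whitespace tolerated).
#' @return A [kinetic_model()].
#' @examples
#' condition_model("4 J 0-1 h")$t_elong / condition_model("0 J")$t_elong
#' @export
condition_model <- function(label) {
  key <- gsub("–|—", "-", label)
  key <- gsub("\\s+", " ", trimws(key))
  baseline <- kinetic_model(0.25, 0.45, 0.30, t_prom = 30,
                            t_elong = 23 * 60)
  in_cis <- kinetic_model(0.20, 0.45, 0.35, t_prom = 30,
                          t_elong = 1.25 * 23 * 60)
  in_trans <- kinetic_model(
    f_free = in_cis$f_free + 0.75 * in_cis$f_prom,
    f_prom = 0.25 * in_cis$f_prom,
    f_elong = in_cis$f_elong,
    t_prom = in_cis$t_prom, t_elong = in_cis$t_elong,
    level_scale = 0.75)
  switch(key,
         "0 J" = baseline,
         "4 J 0-1 h" = in_cis,
         "4 J 1-2 h" = in_trans,
         "4 J 20-21 h" = baseline,
         "16 J 0-1 h" = in_cis,
         stop("unknown condition label: '", label, "'", call. = FALSE))
}

#' Measurement-noise model for synthetic traces
#'
#' @param frame_noise_sd Per-frame additive Gaussian noise in RFI units.
#' @param cell_scale_sd SD (log scale) of the per-cell multiplicative
#'   lognormal variability in expression level; the lognormal is
#'   mean-centred at 1.
#' @param base_level Mean raw pre-bleach intensity of an unperturbed cell
#'   (arbitrary units); per-cell levels are `base_level * level_scale *`
#'   lognormal.
#' @param background_level Constant out-of-strip background in raw units;
#'   `NULL` (default) means 10% of the cohort's mean pre-bleach signal.
#' @param seed Integer seed for cell simulation and noise draws.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(frame_noise_sd = 2, cell_scale_sd = 0.1,
                       base_level = 1000, background_level = NULL,
                       seed = 1L) {
  if (frame_noise_sd < 0 || cell_scale_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (base_level <= 0) stop("base_level must be > 0", call. = FALSE)
  if (!is.null(background_level) && background_level < 0)
    stop("background_level must be >= 0", call. = FALSE)
  structure(
    list(frame_noise_sd = frame_noise_sd, cell_scale_sd = cell_scale_sd,
         base_level = base_level, background_level = background_level,
         seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' Generate noisy per-cell strip-FRAP traces from a kinetic model
#'
#' For each cell a noise-free recovery curve is simulated with a distinct
#' seed, scaled by a per-cell lognormal expression level times the model's
#' `level_scale`, converted to raw intensity units, and overlaid with a
#' constant background and per-frame Gaussian measurement noise. The
#' resulting traces are valid inputs for the preprocessing chain, so the
#' whole pipeline can be exercised end to end against known ground truth.
#'
#' @param model A [kinetic_model()] (e.g. from [condition_model()]).
#' @param noise A [noise_spec()].
#' @param n_cells Number of cells to generate (>= 1).
#' @param sim A [simulation_config()].
#' @param condition Condition label stamped on each trace.
#' @return A list of [frap_trace()] objects; the generating model is
#'   attached as attribute `ground_truth`.
#' @export
generate_cells <- function(model, noise, n_cells, sim,
                           condition = "synthetic") {
  stopifnot(inherits(model, "kinetic_model"), inherits(noise, "noise_spec"),
            inherits(sim, "simulation_config"))
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  acq <- sim$acquisition
  bg <- if (is.null(noise$background_level))
    0.1 * noise$base_level * model$level_scale else noise$background_level
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  traces <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    curve <- simulate_frap(model, sim, seed = noise$seed + i)
    n <- length(curve$rfi)
    set.seed(noise$seed + 100003L * i)
    scale_i <- if (noise$cell_scale_sd > 0)
      rlnorm(1, meanlog = -noise$cell_scale_sd^2 / 2,
             sdlog = noise$cell_scale_sd) else 1
    level_i <- noise$base_level * model$level_scale * scale_i
    raw <- curve$rfi / 100 * level_i + bg +
      rnorm(n, 0, noise$frame_noise_sd * level_i / 100)
    traces[[i]] <- frap_trace(
      cell_id = sprintf("%s_cell%02d", gsub("\\s+", "", condition), i),
      times = (seq_len(n) - 1) * acq$frame_interval,
      strip_intensity = pmax(raw, 0),
      background_intensity = rep(bg, n),
      bleach_frame = acq$n_prebleach + 1L,
      condition = condition)
  }
  attr(traces, "ground_truth") <- model
  traces
}
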
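#' Default end-to-end UV-damage scenario
#'
#' The desk-scale configuration used throughout the package's own analyses:
#' three conditions (unperturbed, first and second hour after 4 J/m^2 UV),
#' 10 cells per condition at the default noise level, the standard
#' acquisition protocol (0.4 s frames, 25 pre-bleach frames, 4 min
#' recovery), 10^4 particles per simulation, and a fitting grid that
#' brackets all three generating models (six elongating residence times
#' crossed with three values of each remaining parameter, two replicate
#' seeds per grid point).
#'
#' @param seed Integer base seed; every stochastic stage derives its seed
#'   from it.
#' @return A nested configuration list accepted by [run_scenario()].
#' @export
default_scenario <- function(seed = 1L) {
  list(
    conditions = c("0 J", "4 J 0-1 h", "4 J 1-2 h"),
    reference = "0 J",
    n_cells = 10L,
    seed = as.integer(seed),
    noise = list(frame_noise_sd = 2, cell_scale_sd = 0.1, base_level = 1000),
    acquisition = list(frame_interval = 0.4, n_prebleach = 25L,
                       recovery_duration = 240, bleach_depth = 0.85),
    geometry = list(semi_axes = c(10, 5, 2.5), strip_width = 1.5),
    sim = list(n_particles = 10000L, cell_particles = 50000L, dt = 0.04),
    D = 2.0,
    calibrate_bleach = TRUE,
    grid = list(
      f_prom = c(0.1125, 0.28, 0.45),
      f_elong = c(0.25, 0.30, 0.35),
      t_prom = c(15, 30, 60),
      t_elong = c(18, 20, 23, 25, 28.75, 32) * 60,
      n_replicates = 8L,
      control_particles = 70000L),
    n_best = 20L
  )
}

#' Run a full synthetic strip-FRAP scenario
#'
#' Orchestrates the whole chain for every condition in the configuration:
#' generate noisy per-cell traces from the condition's ground-truth model,
#' preprocess and average them, calibrate the bleach depth on the reference
#' condition, fit every condition mean on one shared simulated grid, and
#' compare each condition against the reference. Deterministic given the
#' configuration's seed.
#'
#' @param config A configuration list as produced by [default_scenario()],
#'   or a path to a YAML file holding one.
#' @param out_dir Optional output directory; when given, traces, curves,
#'   fit summaries, condition deltas, a curve figure and a run manifest are
#'   written beneath it.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `mean_curves`, `level_summary`, `fits`,
#'   `deltas` (NULL for a single-condition scenario), `bleach_depth` and
#'   `manifest`.
#' @export
run_scenario <- function(config = default_scenario(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  if (length(cfg$conditions) < 1) stop("no conditions configured", call. = FALSE)
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()

  acq <- acquisition_config(frame_interval = cfg$acquisition$frame_interval,
                            n_prebleach = cfg$acquisition$n_prebleach,
                            recovery_duration = cfg$acquisition$recovery_duration,
                            bleach_depth = cfg$acquisition$bleach_depth)
  geom <- geometry_config(semi_axes = cfg$geometry$semi_axes,
                          strip_width = cfg$geometry$strip_width)
  cell_particles <- if (!is.null(cfg$sim$cell_particles))
    cfg$sim$cell_particles else cfg$sim$n_particles
  sim <- simulation_config(n_particles = cell_particles, dt = cfg$sim$dt,
                           geometry = geom, acquisition = acq)
  ref_idx <- reference_indices(acq)

  files <- character(0)
  emit <- function(x, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    if (grepl("\\.json$", name)) {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else {
      write_frap_csv(x, path)
    }
    files[[length(files) + 1L]] <<- path
    invisible(path)
  }

  # Stage 1-2: generate, preprocess, average per condition.
  seeds <- list()
  curves <- list()
  mean_curves <- list()
  all_norm <- list()
  for (k in seq_along(cfg$conditions)) {
    label <- cfg$conditions[[k]]
    model <- condition_model(label)
    cohort_seed <- cfg$seed + 10000L * k
    seeds[[label]] <- cohort_seed
    nz <- noise_spec(frame_noise_sd = cfg$noise$frame_noise_sd,
                     cell_scale_sd = cfg$noise$cell_scale_sd,
                     base_level = cfg$noise$base_level, seed = cohort_seed)
    say(sprintf("[synth] %s: %d cells (seed %d)", label, cfg$n_cells,
                cohort_seed))
    traces <- tryCatch(
      generate_cells(model, nz, cfg$n_cells, sim, condition = label),
      error = function(e) stop("stage synth failed for '", label, "': ",
                               conditionMessage(e), call. = FALSE))
    emit(traces, sprintf("curves/traces_%s.csv", slug(label)))
    norm <- tryCatch(
      preprocess_traces(traces, reference_frames = ref_idx),
      error = function(e) stop("stage preprocess failed for '", label, "': ",
                               conditionMessage(e), call. = FALSE))
    emit(norm, sprintf("curves/normalized_%s.csv", slug(label)))
    curves[[label]] <- norm
    all_norm <- c(all_norm, norm)
    mean_curves[[label]] <- average_curves(norm)
    emit(mean_curves[[label]], sprintf("curves/mean_%s.csv", slug(label)))
  }
  level_summary <- prebleach_level_summary(
    all_norm,
    reference = if (cfg$reference %in% cfg$conditions) cfg$reference else NULL)
  say(paste0("[levels] pre-bleach FI by condition:\n",
             paste(utils::capture.output(print(level_summary)), collapse = "\n")))

  # Stage 3: one shared simulated grid, fit every condition mean.
  ref_label <- if (cfg$reference %in% cfg$conditions) cfg$reference
               else cfg$conditions[[1]]
  bd <- if (isTRUE(cfg$calibrate_bleach))
    calibrate_bleach_depth(mean_curves[[ref_label]]) else acq$bleach_depth
  say(sprintf("[fit] bleach depth %.3f; simulating grid", bd))
  fit_acq <- acquisition_config(frame_interval = acq$frame_interval,
                                n_prebleach = acq$n_prebleach,
                                recovery_duration = acq$recovery_duration,
                                bleach_depth = bd,
                                reference_frames = acq$reference_frames)
  fit_sim <- simulation_config(n_particles = cfg$sim$n_particles,
                               dt = sim$dt, geometry = geom,
                               acquisition = fit_acq)
  grid_seed <- cfg$seed + 900000L
  grid <- parameter_grid(f_prom = cfg$grid$f_prom, f_elong = cfg$grid$f_elong,
                         t_prom = cfg$grid$t_prom, t_elong = cfg$grid$t_elong,
                         n_replicates = cfg$grid$n_replicates,
                         base_seed = grid_seed)
  seeds$grid <- grid_seed
  sims <- simulate_grid(grid, fit_sim, D = cfg$D, progress = !quiet,
                        control_particles = cfg$grid$control_particles)
  fits <- list()
  for (label in cfg$conditions) {
    scored <- grid_fit(mean_curves[[label]], grid, fit_sim, D = cfg$D,
                       simulations = sims)
    fits[[label]] <- select_best(scored, n_best = cfg$n_best)
    say(paste(utils::capture.output(print(fits[[label]])), collapse = "\n"))
    emit(fit_json(fits[[label]]), sprintf("fits/fit_%s.json", slug(label)))
  }

  # Stage 4: condition deltas relative to the reference.
  deltas <- NULL
  others <- setdiff(cfg$conditions, ref_label)
  if (length(others) == 0) {
    say("[compare] single-condition scenario; comparison skipped")
  } else {
    deltas <- do.call(rbind, lapply(others, function(label) {
      d <- compare_conditions(fits[[ref_label]], fits[[label]])
      cbind(reference = ref_label, condition = label, d)
    }))
    say(paste0("[compare] percent change vs ", ref_label, ":\n",
               paste(utils::capture.output(print(deltas)), collapse = "\n")))
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, "deltas.csv")
      write.csv(deltas, path, row.names = FALSE)
      files <- c(files, path)
    }
  }

  if (!is.null(out_dir)) {
    fig <- plot_mean_curves(mean_curves)
    fig_path <- file.path(out_dir, "figures", "mean_curves.png")
    dir.create(dirname(fig_path), recursive = TRUE, showWarnings = FALSE)
    ggplot2::ggsave(fig_path, fig, width = 7, height = 4.5, dpi = 150)
    files <- c(files, fig_path)
  }

  manifest <- list(
    config_hash = config_hash(cfg),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("polfrap")),
    bleach_depth = bd,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = files)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    missing <- files[!file.exists(files)]
    if (length(missing) > 0)
      stop("manifest lists outputs that were not written: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }

  invisible(list(mean_curves = mean_curves, level_summary = level_summary,
                 fits = fits, deltas = deltas, bleach_depth = bd,
                 manifest = manifest))
}

slug <- function(label) gsub("[^A-Za-z0-9]+", "_", label)

fit_json <- function(fit) {
  list(condition = fit$condition, n_best = fit$n_best,
       params = fit$params, best_scores = fit$scores)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Plot condition-averaged recovery curves
#'
#' @param mean_curves Named list of `frap_mean_curve` objects.
#' @return A ggplot: RFI over time with an SD ribbon per condition.
#' @export
plot_mean_curves <- function(mean_curves) {
  if (inherits(mean_curves, "frap_mean_curve"))
    mean_curves <- list(mean_curves)
  df <- do.call(rbind, lapply(mean_curves, frap_as_df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$rfi_mean,
                                   colour = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rfi_mean - .data$rfi_sd,
                                      ymax = .data$rfi_mean + .data$rfi_sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after bleach (s)", y = "RFI",
                  colour = "condition", fill = "condition") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
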
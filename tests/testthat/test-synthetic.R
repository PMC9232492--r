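test_that("condition models encode the UV-scenario kinetics", {
  labels <- c("0 J", "4 J 0-1 h", "4 J 1-2 h", "4 J 20-21 h", "16 J 0-1 h")
  for (lab in labels) {
    m <- condition_model(lab)
    expect_equal(m$f_free + m$f_prom + m$f_elong, 1, tolerance = 1e-12)
    # Published bounds: promoter-bound residence under a minute, elongating
    # residence above 20 min.
    expect_lt(m$t_prom, 60)
    expect_gt(m$t_elong, 20 * 60)
  }

  base <- condition_model("0 J")
  cis <- condition_model("4 J 0-1 h")
  trans <- condition_model("4 J 1-2 h")
  expect_equal(cis$t_elong / base$t_elong, 1.25)
  expect_equal(trans$f_prom / base$f_prom, 0.25)
  expect_equal(trans$level_scale, 0.75)
  expect_equal(condition_model("4 J 20-21 h")$t_elong, base$t_elong)

  # En dashes and spacing are tolerated in labels.
  expect_equal(condition_model("4 J 0–1 h")$t_elong, cis$t_elong)
  expect_error(condition_model("9000 J"), "unknown condition")
})

test_that("zero-noise generation round-trips exactly through preprocessing", {
  m <- condition_model("0 J")
  s <- tiny_sim(n = 1500, recovery = 16)
  nz <- noise_spec(frame_noise_sd = 0, cell_scale_sd = 0, seed = 81)
  traces <- generate_cells(m, nz, n_cells = 1, s, condition = "0 J")
  ref <- simulate_frap(m, s, seed = nz$seed + 1)  # the generating curve
  curve <- preprocess_traces(traces, reference_frames = 4:9)[[1]]
  expect_equal(curve$rfi, ref$rfi, tolerance = 1e-9)
  expect_equal(curve$times, ref$times, tolerance = 1e-9)
  expect_equal(curve$prebleach_fi, 1000, tolerance = 1e-6)
})

test_that("cohort averages track the noise-free curve within sampling error", {
  m <- condition_model("0 J")
  # Enough particles that slow per-simulation counting drift sits well
  # below the framewise bound being tested.
  s <- tiny_sim(n = 8000, recovery = 16)
  nz <- noise_spec(seed = 82)
  traces <- generate_cells(m, nz, n_cells = 10, s, condition = "0 J")
  mc <- average_curves(preprocess_traces(traces, reference_frames = 4:9))

  # Reference ensemble at the same particle count, so its stratification
  # structure matches the cells'.
  ref_runs <- vapply(991:998, function(sd_)
    simulate_frap(m, s, seed = sd_)$rfi, numeric(length(mc$times)))
  ref <- rowMeans(ref_runs)
  ref_sem <- apply(ref_runs, 1, sd) / sqrt(ncol(ref_runs))
  post <- mc$times >= 0
  sem <- mc$rfi_sd[post] / sqrt(mc$n_cells)
  dev <- abs(mc$rfi_mean[post] - ref[post])
  # 3 x the combined standard error of the two framewise means.
  expect_true(all(dev <= 3 * sqrt(sem^2 + ref_sem[post]^2) + 0.5))
})

test_that("the level_scale of a cohort shows up in pre-bleach intensities", {
  base <- condition_model("0 J")
  dimmed <- condition_model("4 J 1-2 h")
  s <- tiny_sim(n = 1000, recovery = 8)
  nz <- noise_spec(cell_scale_sd = 0, frame_noise_sd = 0, seed = 83)
  cells <- c(
    preprocess_traces(generate_cells(base, nz, 3, s, condition = "0 J"),
                      reference_frames = 4:9),
    preprocess_traces(generate_cells(dimmed, nz, 3, s, condition = "4 J 1-2 h"),
                      reference_frames = 4:9))
  lv <- prebleach_level_summary(cells, reference = "0 J")
  expect_equal(lv$rel_mean[lv$condition == "4 J 1-2 h"], 0.75,
               tolerance = 1e-9)
})

test_that("generated traces fit the raw-trace contract", {
  m <- condition_model("4 J 1-2 h")
  s <- tiny_sim(n = 1000, recovery = 8)
  traces <- generate_cells(m, noise_spec(seed = 84), 4, s,
                           condition = "4 J 1-2 h")
  expect_length(traces, 4)
  for (tr in traces) {
    expect_s3_class(tr, "frap_trace")
    expect_true(all(tr$strip_intensity >= 0))
    expect_equal(tr$bleach_frame, s$acquisition$n_prebleach + 1L)
  }
  expect_identical(attr(traces, "ground_truth"), m)
  # Distinct seeds per cell: traces differ.
  expect_false(identical(traces[[1]]$strip_intensity,
                         traces[[2]]$strip_intensity))
})

test_that("generation-fit round trip recovers the generating grid point", {
  truth <- kinetic_model(0.3, 0.4, 0.3, t_prom = 5, t_elong = 60)
  s <- tiny_sim(n = 3000, recovery = 30)
  nz <- noise_spec(seed = 85)
  traces <- generate_cells(truth, nz, n_cells = 6, s, condition = "rt")
  mc <- average_curves(preprocess_traces(traces, reference_frames = 4:9))
  g <- parameter_grid(f_prom = c(0.2, 0.4, 0.6), f_elong = 0.3,
                      t_prom = 5, t_elong = c(30, 60, 120), base_seed = 86)
  best <- select_best(grid_fit(mc, g, s), n_best = 3)
  te <- best$params$mean[best$params$parameter == "t_elong"]
  fp <- best$params$mean[best$params$parameter == "f_prom"]
  # Within one grid step of the generating values.
  expect_gte(te, 30); expect_lte(te, 120)
  expect_gte(fp, 0.2); expect_lte(fp, 0.6)
})
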
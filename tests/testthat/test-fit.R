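flat_curve <- function(rfi_post, acq = tiny_acquisition(), cond = "m") {
  times <- polfrap:::frame_times(acq)
  rfi <- c(rep(100, acq$n_prebleach), rfi_post)
  structure(list(condition = cond, times = times, rfi_mean = rfi,
                 rfi_sd = rep(0, length(rfi)), n_cells = 1L),
            class = "frap_mean_curve")
}

test_that("the SSE score is exact, symmetric and grid-checked", {
  acq <- tiny_acquisition()
  n_post <- polfrap:::n_recovery_frames(acq) + 1L
  a <- flat_curve(rep(50, n_post))
  b <- flat_curve(rep(51, n_post))
  expect_equal(score_curve(a, a), 0)
  expect_equal(score_curve(a, b), n_post)
  expect_equal(score_curve(a, b), score_curve(b, a))

  short <- flat_curve(rep(50, n_post - 5),
                      tiny_acquisition(recovery = 18))
  expect_error(score_curve(a, short), "time grid")
})

test_that("parameter grids validate fractions and carry per-row seeds", {
  expect_error(parameter_grid(f_prom = 0.8, f_elong = 0.5, t_prom = 30,
                              t_elong = 600), "free fraction")
  expect_error(parameter_grid(f_prom = numeric(0), f_elong = 0.3,
                              t_prom = 30, t_elong = 600), "at least one")

  g <- parameter_grid(f_prom = c(0.2, 0.4), f_elong = 0.3,
                      t_prom = c(20, 40), t_elong = c(600, 1200),
                      n_replicates = 2, base_seed = 50)
  expect_equal(nrow(g), 16)
  expect_equal(g$f_free, 1 - g$f_prom - g$f_elong)
  # Common random numbers: one seed per replicate, shared by every grid
  # point, and a function of the replicate rather than the row position.
  expect_identical(unique(g$seed[g$replicate == 1]), 50L)
  expect_identical(unique(g$seed[g$replicate == 2]), 51L)
  g2 <- g[rev(seq_len(nrow(g))), ]
  expect_identical(g2$seed, rev(g$seed))
})

test_that("grid fitting scores every entry and sorts deterministically", {
  m <- condition_model("0 J")
  s <- tiny_sim(n = 1200, recovery = 16)
  target <- as_mean_curve(simulate_frap(m, s, seed = 41))

  g1 <- parameter_grid(f_prom = m$f_prom, f_elong = m$f_elong,
                       t_prom = m$t_prom, t_elong = m$t_elong,
                       base_seed = 60)
  scored1 <- grid_fit(target, g1, s)
  expect_s3_class(scored1, "frap_scored")
  expect_equal(nrow(scored1), 1)
  expect_gte(scored1$score, 0)

  g <- parameter_grid(f_prom = c(0.15, 0.45), f_elong = c(0.2, 0.3),
                      t_prom = 30, t_elong = c(600, 1380), base_seed = 61)
  scored <- grid_fit(target, g, s)
  expect_equal(nrow(scored), 8)
  expect_true(!is.unsorted(scored$score))

  # Permuting grid order leaves the sorted result unchanged (seeds travel
  # with their grid points).
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  gp <- g[perm, ]
  class(gp) <- class(g)
  scored_p <- grid_fit(target, gp, s)
  expect_equal(scored_p$score, scored$score)
  expect_equal(scored_p$point_id, scored$point_id)
})

test_that("select_best aggregates the lowest scores with documented ties", {
  m <- condition_model("0 J")
  s <- tiny_sim(n = 1200, recovery = 16)
  target <- as_mean_curve(simulate_frap(m, s, seed = 42))
  g <- parameter_grid(f_prom = c(0.15, 0.45), f_elong = 0.3,
                      t_prom = 30, t_elong = c(600, 1380), base_seed = 62)
  scored <- grid_fit(target, g, s)

  expect_error(select_best(scored, n_best = 10), "fewer than")

  whole <- select_best(scored, n_best = nrow(scored))
  expect_equal(whole$params$mean[whole$params$parameter == "f_prom"],
               mean(scored$f_prom))

  # Duplicating every entry collapses to identical scores and means.
  dup <- rbind(as.data.frame(scored), as.data.frame(scored))
  dup <- dup[order(dup$score), ]
  class(dup) <- class(scored)
  attr(dup, "condition") <- attr(scored, "condition")
  best2 <- select_best(dup, n_best = 4)
  best1 <- select_best(scored, n_best = 2)
  expect_equal(best2$params$mean, best1$params$mean)

  # Equal scores: the earlier enumeration order wins the cutoff.
  tied <- as.data.frame(scored)
  tied$score <- 1
  tied <- tied[order(tied$point_id), ]
  class(tied) <- class(scored)
  attr(tied, "condition") <- "t"
  b <- select_best(tied, n_best = 2)
  expect_equal(sort(b$best$point_id), sort(tied$point_id[1:2]))

  one_model <- select_best(scored, n_best = 1)
  expect_true(all(one_model$params$sd == 0))
})

test_that("the generating model is recovered from a low-noise target", {
  # Scaled-down kinetics so exchange is fast and simulations are cheap.
  truth <- kinetic_model(0.3, 0.4, 0.3, t_prom = 5, t_elong = 60)
  s <- tiny_sim(n = 3000, recovery = 30)
  g <- parameter_grid(f_prom = c(0.2, 0.4, 0.6), f_elong = 0.3,
                      t_prom = 5, t_elong = c(30, 60, 120), base_seed = 70)
  n_rep <- 5
  hits_score <- 0
  hits_step <- 0
  for (r in seq_len(n_rep)) {
    target <- as_mean_curve(simulate_frap(truth, s, seed = 200 + r))
    scored <- grid_fit(target, g, s)
    best <- select_best(scored, n_best = 3)
    top <- scored[seq_len(3), ]
    if (any(top$f_prom == truth$f_prom & top$t_elong == truth$t_elong))
      hits_score <- hits_score + 1
    te <- best$params$mean[best$params$parameter == "t_elong"]
    fp <- best$params$mean[best$params$parameter == "f_prom"]
    if (te >= 30 && te <= 120 && fp >= 0.2 && fp <= 0.6)
      hits_step <- hits_step + 1
  }
  expect_gte(hits_score, n_rep - 1)  # generating model among the best
  expect_gte(hits_step, ceiling(0.9 * n_rep))  # within one grid step
})

test_that("condition comparison reports percent changes and flags zeros", {
  mk_fit <- function(means) {
    structure(list(condition = "x", n_best = 1L,
                   params = data.frame(
                     parameter = c("f_free", "f_prom", "f_elong", "t_prom",
                                   "t_elong"),
                     mean = means, sd = 0),
                   scores = 0, best = NULL),
              class = "frap_fit")
  }
  a <- mk_fit(c(0.25, 0.40, 0.35, 30, 20 * 60))
  expect_true(all(compare_conditions(a, a)$pct_change == 0))

  b <- mk_fit(c(0.25, 0.10, 0.35, 30, 25 * 60))
  d <- compare_conditions(a, b)
  expect_equal(d$pct_change[d$parameter == "t_elong"], 25)
  expect_equal(d$pct_change[d$parameter == "f_prom"], -75)

  z <- mk_fit(c(0.25, 0, 0.35, 30, 20 * 60))
  dz <- compare_conditions(z, b)
  expect_true(dz$undefined[dz$parameter == "f_prom"])
  expect_true(is.na(dz$pct_change[dz$parameter == "f_prom"]))
})

test_that("bleach depth is calibrated from the first post-bleach frame", {
  acq <- tiny_acquisition()
  n_post <- polfrap:::n_recovery_frames(acq) + 1L
  cv <- flat_curve(c(15, rep(60, n_post - 1)))
  expect_equal(calibrate_bleach_depth(cv), 0.85)
})
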
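test_that("initialization respects fractions, geometry and the seed", {
  s <- tiny_sim(n = 1000)
  m_free <- kinetic_model(1, 0, 0, t_prom = 1, t_elong = 1)
  e <- init_population(m_free, s, seed = 3)
  expect_true(all(e$state == 0L))
  expect_true(all(e$fluorescent))

  ax <- s$geometry$semi_axes
  r2 <- (e$positions[, 1] / ax[1])^2 + (e$positions[, 2] / ax[2])^2 +
    (e$positions[, 3] / ax[3])^2
  expect_true(all(r2 <= 1 + 1e-12))

  # Binomial bound on the sampled state shares at large n.
  m_half <- kinetic_model(0.5, 0.5, 0, t_prom = 10, t_elong = 10)
  big <- init_population(m_half, tiny_sim(n = 100000), seed = 4)
  n_prom <- sum(big$state == 1L)
  expect_lt(abs(n_prom - 50000), 4 * sqrt(100000 * 0.25))

  e2 <- init_population(m_free, s, seed = 3)
  expect_identical(e$positions, e2$positions)
  expect_identical(e$state, e2$state)
})

test_that("free diffusion follows the Einstein relation and D = 0 freezes", {
  frozen <- kinetic_model(1, 0, 0, t_prom = 1, t_elong = 1, D = 1e-12)
  s <- tiny_sim(n = 500)
  e <- init_population(frozen, s, seed = 5)
  e2 <- step_particles(e, frozen, dt = 0.02, n_steps = 50, seed = 6)
  expect_equal(e2$positions, e$positions, tolerance = 1e-4)

  # Oversized nucleus so boundary reflection is negligible: per-axis MSD
  # after time t is 2 D t.
  m <- kinetic_model(1, 0, 0, t_prom = 1, t_elong = 1, D = 2)
  huge <- simulation_config(n_particles = 3000, dt = 0.02,
                            geometry = geometry_config(c(500, 500, 500), 1.5),
                            acquisition = tiny_acquisition())
  e0 <- init_population(m, huge, seed = 7)
  t_total <- 1.0
  e1 <- step_particles(e0, m, dt = 0.02, n_steps = 50, seed = 8)
  disp2 <- (e1$positions - e0$positions)^2
  expected <- 2 * 2 * t_total
  se <- expected * sqrt(2 / length(disp2))
  expect_lt(abs(mean(disp2) - expected), 4 * se)
})

test_that("vanishing exchange rates freeze the kinetic states", {
  m <- kinetic_model(0.4, 0.3, 0.3, t_prom = 1e12, t_elong = 1e12, D = 2)
  s <- tiny_sim(n = 1000)
  e <- init_population(m, s, seed = 9)
  e2 <- step_particles(e, m, dt = 0.02, n_steps = 200, seed = 10)
  expect_identical(e2$state, e$state)
})

test_that("bleaching darkens in-strip particles with the given probability", {
  m <- kinetic_model(0.3, 0.4, 0.3, t_prom = 30, t_elong = 600)
  e <- init_population(m, tiny_sim(n = 100000), seed = 11)

  full <- bleach_ensemble(e, bleach_depth = 1, seed = 12)
  expect_identical(readout_strip(full), 0L)

  none <- bleach_ensemble(e, bleach_depth = 0, seed = 12)
  expect_identical(none$fluorescent, e$fluorescent)

  part <- bleach_ensemble(e, bleach_depth = 0.7, seed = 13)
  n_strip <- readout_strip(e)
  survivors <- readout_strip(part)
  expect_lt(abs(survivors - 0.3 * n_strip), 4 * sqrt(n_strip * 0.7 * 0.3))

  dark <- e; dark$fluorescent[] <- FALSE
  expect_identical(readout_strip(dark), 0L)
})

test_that("unbleached readout matches the strip volume fraction", {
  m <- kinetic_model(1, 0, 0, t_prom = 1, t_elong = 1)
  s <- tiny_sim(n = 200000)
  e <- init_population(m, s, seed = 14)
  ax <- s$geometry$semi_axes
  w <- s$geometry$strip_width
  # Slab through an ellipsoid: V_slab / V = (3/4) (w/a) (1 - w^2 / (12 a^2)).
  vfrac <- 0.75 * (w / ax[1]) * (1 - w^2 / (12 * ax[1]^2))
  expect_lt(abs(readout_strip(e) - s$n_particles * vfrac),
            4 * sqrt(s$n_particles * vfrac * (1 - vfrac)))
})

test_that("simulated curves are seed-deterministic and physically shaped", {
  m <- condition_model("0 J")
  s <- tiny_sim(n = 2000, recovery = 20)
  a <- simulate_frap(m, s, seed = 21)
  b <- simulate_frap(m, s, seed = 21)
  expect_identical(a$rfi, b$rfi)
  expect_identical(a$counts, b$counts)
  c_ <- simulate_frap(m, s, seed = 22)
  expect_false(identical(a$rfi, c_$rfi))

  expect_equal(a$times[s$acquisition$n_prebleach + 1], 0)
  expect_true(all(a$rfi >= 0))
  # tiny acquisition reference window: pre-bleach frames 3-8 (0-based)
  expect_equal(mean(a$rfi[4:9]), 100, tolerance = 1e-9)
})

test_that("a fully immobile pool never recovers after a complete bleach", {
  m <- kinetic_model(0, 0, 1, t_prom = 1, t_elong = 1e12)
  s <- tiny_sim(n = 3000, recovery = 20, bleach_depth = 1)
  cv <- simulate_frap(m, s, seed = 23)
  post <- cv$rfi[cv$times >= 0]
  expect_true(all(post == post[1]))
  expect_equal(post[1], 0)
})

test_that("a purely mobile pool recovers to the unbleached share", {
  # Fast diffusion in a small nucleus mixes the pool well within the
  # recovery window; the asymptote is 100 x (fluorescent / total).
  m <- kinetic_model(1, 0, 0, t_prom = 1, t_elong = 1, D = 20)
  s <- simulation_config(n_particles = 20000, dt = 0.01,
                         geometry = geometry_config(c(6, 4, 2.5), 1.5),
                         acquisition = tiny_acquisition(recovery = 30))
  cv <- simulate_frap(m, s, seed = 24)
  expected <- 100 * (s$n_particles - cv$n_bleached) / s$n_particles
  tail_mean <- mean(cv$rfi[cv$times > 20])
  expect_lt(abs(tail_mean - expected), 2)
})

test_that("the fixed-dwell elongating option also reaches steady state", {
  m <- kinetic_model(0.5, 0, 0.5, t_prom = 1, t_elong = 4,
                     elongating_dwell = "fixed")
  s <- tiny_sim(n = 5000, recovery = 30)
  cv <- simulate_frap(m, s, seed = 25)
  # Pre-bleach signal stationary: no drift across the pre-bleach block.
  pre <- cv$rfi[cv$times < 0]
  expect_lt(abs(mean(pre[1:5]) - mean(pre[6:10])), 5)
  expect_true(all(is.finite(cv$rfi)))
})
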
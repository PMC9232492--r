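make_trace <- function(strip, background = rep(0, length(strip)),
                       bleach_frame = length(strip), dt = 0.4,
                       condition = "0 J") {
  frap_trace(cell_id = "c1", times = (seq_along(strip) - 1) * dt,
             strip_intensity = strip, background_intensity = background,
             bleach_frame = bleach_frame, condition = condition)
}

test_that("trace construction validates its inputs", {
  expect_error(frap_trace("c", numeric(0), numeric(0), numeric(0), 1),
               "empty")
  expect_error(make_trace(c(1, 2, 3), background = c(1, 2)), "equal length")
  expect_error(frap_trace("c", c(0, 0.4, 0.7), c(1, 1, 1), c(0, 0, 0), 3),
               "uniformly spaced")
  expect_error(make_trace(c(1, -2, 3)), ">= 0")
})

test_that("background correction subtracts elementwise and clips at zero", {
  tr <- make_trace(c(110, 120, 115), background = c(10, 10, 10))
  expect_equal(background_correct(tr)$strip_intensity, c(100, 110, 105))

  tr0 <- make_trace(c(50, 60, 70))
  expect_equal(background_correct(tr0)$strip_intensity, tr0$strip_intensity)

  over <- make_trace(c(5, 100), background = c(8, 0))
  expect_equal(background_correct(over)$strip_intensity, c(0, 100))
})

test_that("pre-bleach normalization pins the reference window to 100", {
  # Constant corrected trace: RFI identically 100, pre-bleach FI retained.
  tr <- background_correct(make_trace(rep(500, 30), bleach_frame = 26))
  cv <- normalize_prebleach(tr)
  expect_equal(cv$rfi, rep(100, 30))
  expect_equal(cv$prebleach_fi, 500)

  # Linear scaling: reference mean 200 maps a post-bleach 90 to RFI 45.
  strip <- c(rep(200, 25), 90, rep(120, 4))
  cv2 <- normalize_prebleach(background_correct(make_trace(strip,
                                                           bleach_frame = 26)))
  expect_equal(cv2$rfi[26], 45)
  expect_equal(cv2$times[26], 0)
  expect_true(all(cv2$times[1:25] < 0))

  # Arbitrary positive trace: the reference-window mean is exactly 100.
  set.seed(5)
  strip3 <- runif(120, 400, 600)
  cv3 <- normalize_prebleach(background_correct(make_trace(strip3,
                                                           bleach_frame = 26)))
  expect_equal(mean(cv3$rfi[11:21]), 100, tolerance = 1e-12)
})

test_that("normalization rejects degenerate and misplaced windows", {
  z <- background_correct(make_trace(rep(0, 30), bleach_frame = 26))
  expect_error(normalize_prebleach(z), "degenerate")
  tr <- background_correct(make_trace(rep(10, 30), bleach_frame = 15))
  expect_error(normalize_prebleach(tr, reference_frames = 11:21),
               "before the bleach frame")
})

test_that("normalization is idempotent and gain-invariant", {
  set.seed(7)
  strip <- runif(80, 300, 500)
  bg <- runif(80, 20, 40)
  base <- normalize_prebleach(background_correct(
    make_trace(strip, background = bg, bleach_frame = 26)))

  # Feeding the normalized RFI back through normalization changes nothing.
  again <- normalize_prebleach(background_correct(
    make_trace(base$rfi, bleach_frame = 26)))
  expect_equal(again$rfi, base$rfi, tolerance = 1e-9)

  # Multiplying strip and background by any gain leaves the RFI unchanged.
  for (gain in c(0.2, 7.5)) {
    scaled <- normalize_prebleach(background_correct(
      make_trace(gain * strip, background = gain * bg, bleach_frame = 26)))
    expect_equal(scaled$rfi, base$rfi, tolerance = 1e-9)
  }
})

test_that("curve averaging returns pointwise mean and sample SD", {
  strip <- c(rep(100, 25), 40, seq(41, 60, length.out = 10))
  cv <- normalize_prebleach(background_correct(make_trace(strip,
                                                          bleach_frame = 26)))
  m <- average_curves(list(cv, cv, cv))
  expect_equal(m$rfi_mean, cv$rfi)
  expect_equal(m$rfi_sd, rep(0, length(cv$rfi)))
  expect_equal(m$n_cells, 3L)

  lo <- cv; lo$rfi[30] <- 80
  hi <- cv; hi$rfi[30] <- 120
  m2 <- average_curves(list(lo, hi))
  expect_equal(m2$rfi_mean[30], 100)
  expect_equal(m2$rfi_sd[30], sd(c(80, 120)))

  expect_error(average_curves(list()), "empty")
  shifted <- cv; shifted$times <- cv$times + 0.2
  expect_error(average_curves(list(cv, shifted)), "common time grid")

  short <- cv
  short$times <- cv$times[1:30]; short$rfi <- cv$rfi[1:30]
  expect_warning(m3 <- average_curves(list(cv, short)), "truncating")
  expect_length(m3$rfi_mean, 30)
})

test_that("pre-bleach level summary reports mean, SD and relative levels", {
  mk <- function(fi, cond) {
    cv <- normalize_prebleach(background_correct(
      make_trace(rep(fi, 30), bleach_frame = 26, condition = cond)))
    cv
  }
  s1 <- prebleach_level_summary(list(mk(100, "a"), mk(100, "a"), mk(100, "a")))
  expect_equal(s1$mean_fi, 100)
  expect_equal(s1$sd_fi, 0)

  s2 <- prebleach_level_summary(list(mk(120, "solo")))
  expect_equal(s2$mean_fi, 120)
  expect_equal(s2$sd_fi, 0)

  s3 <- prebleach_level_summary(
    list(mk(200, "ref"), mk(220, "ref"), mk(150, "uv"), mk(165, "uv")),
    reference = "ref")
  expect_equal(s3$rel_mean[s3$condition == "ref"], 1)
  expect_equal(s3$rel_mean[s3$condition == "uv"], 157.5 / 210)
  expect_error(prebleach_level_summary(list(), reference = "x"), "empty")
})

test_that("traces round-trip through the long-format CSV interface", {
  set.seed(11)
  traces <- lapply(1:3, function(i)
    frap_trace(cell_id = paste0("cell", i), times = (0:39) * 0.4,
               strip_intensity = runif(40, 100, 300),
               background_intensity = runif(40, 5, 15),
               bleach_frame = 26, condition = "0 J"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_frap_csv(traces, path)
  back <- read_frap_traces(path)
  expect_length(back, 3)
  got <- back[["cell2"]]
  want <- traces[[2]]
  expect_equal(got$strip_intensity, want$strip_intensity, tolerance = 1e-8)
  expect_equal(got$background_intensity, want$background_intensity,
               tolerance = 1e-8)
  expect_equal(got$bleach_frame, want$bleach_frame)
  expect_equal(got$condition, want$condition)
})
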
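test_that("pure tones are classified by period with the 4*A*f downslope", {
  # 0.7 Hz, 35 uV: period 1.43 s in the SO window, slope 98 uV/s
  x <- smooth_moving_average(sine(0.7, 35, dur = 60), FS)
  hw <- detect_halfwaves(x, FS)
  expect_true(all(hw$band == "SO"))
  expect_equal(mean(hw$downslope), 98, tolerance = 98 * 0.05)
  expect_true(all(hw$t_trough > hw$t_zero_cross))
  expect_true(all(hw$trough_amp <= -5))

  # 2 Hz, 20 uV: period 0.5 s in the delta window, slope 160 uV/s
  x2 <- smooth_moving_average(sine(2, 20, dur = 60), FS)
  hw2 <- detect_halfwaves(x2, FS)
  expect_true(all(hw2$band == "delta"))
  expect_equal(mean(hw2$downslope), 160, tolerance = 160 * 0.05)
})

test_that("amplitude threshold and duration windows gate detections", {
  # 4 uV trough stays above the -5 uV threshold: nothing detected
  expect_equal(nrow(detect_halfwaves(sine(0.7, 4, dur = 60), FS)), 0)
  expect_gt(nrow(detect_halfwaves(sine(0.7, 6, dur = 60), FS)), 0)
  # 0.1 Hz: period 10 s, outside both duration windows
  expect_equal(nrow(detect_halfwaves(sine(0.1, 50, dur = 60), FS)), 0)
  # 5 Hz: period 0.2 s, just below the delta window
  expect_equal(nrow(detect_halfwaves(sine(5, 50, dur = 60), FS)), 0)
  # signals shorter than 2 s yield an empty set
  expect_equal(nrow(detect_halfwaves(sine(2, 50, dur = 1), FS)), 0)
})

test_that("a more negative threshold never increases the detection count", {
  set.seed(5)
  x <- smooth_moving_average(
    sine(0.7, 12, dur = 60) + sine(2, 8, dur = 60, phase = 1) + rnorm(60 * FS, 0, 2),
    FS)
  counts <- vapply(c(-2, -5, -8, -12), function(th)
    nrow(detect_halfwaves(x, FS, amp_threshold = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is robust to a small fast ripple", {
  base <- smooth_moving_average(sine(0.7, 35, dur = 60), FS)
  rippled <- smooth_moving_average(sine(0.7, 35, dur = 60) + sine(20, 2, dur = 60), FS)
  hw0 <- detect_halfwaves(base, FS)
  hw1 <- detect_halfwaves(rippled, FS)
  expect_equal(nrow(hw1), nrow(hw0))
  expect_equal(mean(hw1$downslope), mean(hw0$downslope),
               tolerance = 0.03 * mean(hw0$downslope))
})

test_that("vectorized detector matches an independent loop-based oracle", {
  set.seed(17)
  for (i in 1:3) {
    x <- smooth_moving_average(
      sine(0.7, 20, dur = 60, phase = stats::runif(1, 0, 2 * pi)) +
        sine(2.2, 12, dur = 60, phase = stats::runif(1, 0, 2 * pi)) +
        rnorm(60 * FS, 0, 3),
      FS)
    got <- detect_halfwaves(x, FS)
    exp <- oracle_halfwaves(x, FS)
    expect_equal(nrow(got), nrow(exp))
    expect_equal(got$band, exp$band)
    expect_equal(got$t_zero_cross, exp$t_zero_cross, tolerance = 1e-9)
    expect_equal(got$t_trough, exp$t_trough, tolerance = 1e-9)
    expect_equal(got$trough_amp, exp$trough_amp, tolerance = 1e-12)
  }
})

test_that("the literal half-wave separation criterion is available", {
  # 0.35 Hz: negative half-wave lasts 1.43 s -> SO under the half-wave
  # reading, rejected under the default period reading (period ~2.9 s)
  x <- smooth_moving_average(sine(0.35, 35, dur = 120), FS)
  expect_equal(nrow(detect_halfwaves(x, FS, criterion = "period")), 0)
  hw <- detect_halfwaves(x, FS, criterion = "halfwave")
  expect_true(all(hw$band == "SO"))
})

test_that("slope summaries pool per-epoch means over eligible NREM epochs", {
  hw <- tibble::tibble(
    band = c("SO", "SO", "SO", "delta"),
    downslope = c(80, 100, 110, 150),
    epoch_index = c(0L, 0L, 1L, 1L),
    stage = c("N2", "N2", "N3", "N3"),
    portion = "diagnostic", artifact = FALSE
  )
  s <- summarize_slopes(hw)
  # epoch means 90 and 110 -> NREM mean 100, not the detection-weighted 96.7
  expect_equal(s$mean_slope[s$band == "SO"], 100)
  expect_equal(s$n_detections[s$band == "SO"], 3)
  expect_equal(s$mean_slope[s$band == "delta"], 150)
  sw <- summarize_slopes(hw, weight_by_count = TRUE)
  expect_equal(sw$mean_slope[sw$band == "SO"], mean(c(80, 100, 110)))

  # REM/artifact epochs are excluded; empty bands are reported missing
  hw_rem <- dplyr::mutate(hw, stage = "R")
  s2 <- summarize_slopes(hw_rem)
  expect_true(all(is.na(s2$mean_slope)))
  expect_equal(unique(s2$reason), "no detections in eligible epochs")
})

test_that("waves straddling an epoch boundary follow their trough", {
  sim <- synthesize_recording(psg_spec(
    stage_sequence = data.frame(stage = "N3", n_epochs = 4),
    components = list(list(stage = "N3", mode = "sinusoid_train", amplitude = 35,
                           frequency = 0.7, density = 10, cycles = 2)),
    noise_floor = list(scale = 0.5, exponent = 1), seed = 23))
  hw <- compute_slope_features(sim$recording, sim$hypnogram)
  expect_true(all(hw$epoch_index == floor(hw$t_trough / 30)))
})

test_that("decaying slow-wave amplitude lowers later-period mean slopes", {
  mk_train <- function(amp) list(stage = "N3", mode = "sinusoid_train",
                                 amplitude = amp, frequency = 0.7,
                                 density = 10, cycles = 2)
  # two N3 blocks; inject 35 uV trains in both, then rescale second block by 0.8
  sim <- synthesize_recording(psg_spec(
    stage_sequence = data.frame(stage = "N3", n_epochs = 20),
    components = list(mk_train(35)),
    noise_floor = list(scale = 0, exponent = 1), seed = 9))
  x <- sim$recording$channels$Fz
  half <- length(x) / 2
  x[(half + 1):length(x)] <- 0.8 * x[(half + 1):length(x)]
  rec <- tiny_recording(x)
  hw <- compute_slope_features(rec, sim$hypnogram)
  early <- summarize_slopes(hw[hw$epoch_index < 10, ])
  late <- summarize_slopes(hw[hw$epoch_index >= 10, ])
  expect_gt(early$mean_slope[early$band == "SO"],
            late$mean_slope[late$band == "SO"])
})
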
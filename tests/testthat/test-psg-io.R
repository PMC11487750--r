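test_that("EDF write/read round-trips samples to quantization precision", {
  set.seed(11)
  n <- FS * 60
  rec <- psg_recording(
    list(Fz = 50 * sin(2 * pi * 1.3 * (0:(n - 1)) / FS) + rnorm(n, 0, 5),
         Cz = rnorm(n, 0, 10)),
    fs = FS
  )
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  rec2 <- read_edf(f)
  expect_equal(rec2$fs, FS)
  expect_equal(length(rec2$channels$Fz), n)   # 60 s at 500 Hz -> 30 000 samples
  for (ch in names(rec$channels)) {
    step <- diff(range(rec$channels[[ch]])) / 65535
    expect_lt(max(abs(rec2$channels[[ch]] - rec$channels[[ch]])), step)
  }
})

test_that("read_edf selects channels and errors informatively on unknown labels", {
  rec <- tiny_recording(sine(2, 20, dur = 30))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  got <- read_edf(f, channels = c("Fz", "Cz"))
  expect_named(got$channels, c("Fz", "Cz"))
  expect_error(read_edf(f, channels = "Pz"), "Available.*Fz")
})

test_that("header sampling rate is passed through even when it is not 500 Hz", {
  rec <- psg_recording(list(Fz = sine(2, 10, dur = 10, fs = 256)), fs = 256)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  expect_equal(read_edf(f)$fs, 256)
})

test_that("derivation subtracts the reference average and is linear", {
  rec <- psg_recording(list(Fz = rep(10, 4), A1 = rep(2, 4), A2 = rep(4, 4)),
                       fs = 1)
  expect_equal(make_derivation(rec, "Fz", c("A1", "A2")), rep(7, 4))

  x <- sine(3, 12, dur = 2)
  rec2 <- psg_recording(list(Fz = x, Cz = numeric(length(x))), fs = FS)
  expect_equal(make_derivation(rec2, "Fz", "Cz"), x)          # identity reference
  rec3 <- psg_recording(list(Fz = x, A1 = x, A2 = x), fs = FS)
  expect_equal(make_derivation(rec3, "Fz", c("A1", "A2")), numeric(length(x)))
  # linearity
  rec4 <- psg_recording(list(Fz = 3 * x, Cz = numeric(length(x))), fs = FS)
  expect_equal(make_derivation(rec4, "Fz", "Cz"), 3 * make_derivation(rec2, "Fz", "Cz"))
  expect_error(make_derivation(rec2, "Fz", character()), "at least one")
  expect_error(make_derivation(rec2, "Oz", "Cz"), "Available")
})

test_that("parse_derivation handles both dialects", {
  expect_equal(parse_derivation("Fz-Cz"), list(positive = "Fz", references = "Cz"))
  expect_equal(parse_derivation("Fz:(A1,A2)"),
               list(positive = "Fz", references = c("A1", "A2")))
})

test_that("epoch_slices returns exact 30-s windows and respects alignment", {
  x <- sine(2, 10, dur = 300)
  rec <- tiny_recording(x)
  hyp <- hypnogram(rep(c("N2", "N3"), each = 5))
  ep <- epoch_slices(rec, hyp, "Fz", "Cz")
  expect_equal(nrow(ep), 10)
  expect_true(all(lengths(ep$samples) == 30 * FS))
  # windows tile the hypnogram-covered length exactly
  expect_equal(sum(lengths(ep$samples)), length(x))
  expect_equal(ep$samples[[3]], x[(2 * 30 * FS + 1):(3 * 30 * FS)])

  # trailing partial epoch discarded with a warning
  rec305 <- tiny_recording(sine(2, 10, dur = 305))
  expect_warning(ep2 <- epoch_slices(rec305, hyp, "Fz", "Cz"), "partial")
  expect_equal(nrow(ep2), 10)

  # hypnogram longer than recording is an alignment error
  hyp11 <- hypnogram(rep("N2", 11))
  expect_error(epoch_slices(rec, hyp11, "Fz", "Cz"), "full epochs")

  # artifact flags pass through untouched
  hypa <- hypnogram(rep("N2", 10), artifact = c(TRUE, rep(FALSE, 9)))
  epa <- epoch_slices(rec, hypa, "Fz", "Cz")
  expect_true(epa$artifact[1])
  expect_false(any(epa$artifact[-1]))
})

test_that("hypnogram validation enforces the grid and dialects round-trip", {
  expect_error(hypnogram(c("N2", "Q1")), "Unknown sleep stage")
  expect_error(validate_hypnogram <- hypnogram(rep("N2", 3), epoch_index = c(0, 2, 3)),
               "contiguous")
  h <- hypnogram(c("W", "N1", "N2", "N3", "R"), portion = "diagnostic")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hypnogram(h, f)
  expect_equal(as.data.frame(read_hypnogram(f)), as.data.frame(h))
})

test_that("annotations map onto the 30-s grid by majority stage", {
  ann <- data.frame(onset = c(0, 45, 100), duration = c(45, 55, 80),
                    stage = c("N1", "N2", "N3"))
  h <- hypnogram_from_annotations(ann, n_epochs = 6)
  # epoch 1 (30-60 s): 15 s N1 + 15 s N2, tie -> earlier-starting annotation
  expect_equal(h$stage, c("N1", "N1", "N2", "N3", "N3", "N3"))
  expect_error(hypnogram_from_annotations(ann, n_epochs = 7), "gap")
})

test_that("artifact rejection flags amplitude and flat-line epochs", {
  good <- sine(2, 30, dur = 30)
  spike <- good; spike[100] <- 400
  flat <- c(rep(5, 6 * FS), sine(2, 30, dur = 24))
  rec <- tiny_recording(c(good, spike, flat))
  hyp <- hypnogram(rep("N2", 3))
  ep <- flag_artifacts(epoch_slices(rec, hyp, "Fz", "Cz"), FS)
  expect_equal(ep$artifact, c(FALSE, TRUE, TRUE))
})
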
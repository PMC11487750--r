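# Seeded synthetic polysomnography with analytic ground truth. EEG is built
# as a mixture of band-limited components per sleep stage, so relative band
# power and slow-wave downslopes are known in closed form: a sinusoidal wave
# of amplitude A (uV) and frequency f (Hz) has downslope
# A / (T/4) = 4 * A * f from descending zero-crossing to trough.

#' Specify a synthetic PSG recording
#'
#' @param stage_sequence Tibble/data frame with columns `stage` and
#'   `n_epochs`, in temporal order; defaults to a split-night diagnostic
#'   architecture via [default_stage_sequence()].
#' @param components List of component specs, each a list with fields:
#'   `stage` (which stage it plays in), `mode` (`"sinusoid"` for a continuous
#'   tone, `"sinusoid_train"` for countable multi-cycle slow-wave events,
#'   `"bandlimited_noise"`), `amplitude` (uV; RMS for noise, peak for tones),
#'   `frequency` (Hz; or `f_lo`/`f_hi` for noise), and for trains `density`
#'   (events/min) and `cycles` (full waves per event, default 2).
#' @param noise_floor List with `scale` (uV RMS) and `exponent` (1/f^a
#'   spectral slope); `scale = 0` disables it.
#' @param fs Sampling rate in Hz (default 500).
#' @param portion Study portion label for the hypnogram.
#' @param seed Integer seed; fully determines the output.
#' @return A `psg_spec` list.
#' @export
psg_spec <- function(stage_sequence = default_stage_sequence(),
                     components = default_components(),
                     noise_floor = list(scale = 1.5, exponent = 1),
                     fs = 500, portion = "diagnostic", seed = 1L) {
  ss <- as_tibble(stage_sequence)
  stopifnot(all(c("stage", "n_epochs") %in% names(ss)))
  if (nrow(ss) == 0 || sum(ss$n_epochs) == 0) abort("stage_sequence must be non-empty.")
  for (cm in components) {
    if (!is.null(cm$frequency) && !is.null(cm$amplitude)) {
      if (cm$amplitude < 0) abort("Component amplitudes must be >= 0.")
    }
  }
  structure(list(stage_sequence = ss, components = components,
                 noise_floor = noise_floor, fs = fs, portion = portion,
                 seed = as.integer(seed)),
            class = "psg_spec")
}

#' Default diagnostic-portion sleep architecture
#'
#' Roughly 168 min of sleep with stage shares near N1 25%, N2 48%, N3 16%,
#' REM 11%, laid out as two NREM-REM cycles with some wake.
#'
#' @param tst_min Total sleep time in minutes.
#' @return Tibble with `stage`, `n_epochs`.
#' @export
default_stage_sequence <- function(tst_min = 168) {
  total <- round(tst_min * 2)                   # 30-s epochs
  mix <- c(N1 = 0.25, N2 = 0.48, N3 = 0.16, R = 0.11)
  n <- round(mix * total)
  tibble(
    stage = c("W", "N1", "N2", "N3", "N2", "R", "N1", "N2", "N3", "N2", "R", "W"),
    n_epochs = c(4,
                 ceiling(n["N1"] / 2), ceiling(n["N2"] / 3), ceiling(n["N3"] / 2),
                 floor(n["N2"] / 3), ceiling(n["R"] / 2),
                 floor(n["N1"] / 2), ceiling(n["N2"] / 3), floor(n["N3"] / 2),
                 n["N2"] - ceiling(n["N2"] / 3) * 2 - floor(n["N2"] / 3) + ceiling(n["N2"] / 3),
                 floor(n["R"] / 2), 2)
  )
}

#' @rdname psg_spec
#' @export
#' @details `default_components()` encodes a schematic split-night diagnostic
#'   portion: slow-oscillation trains and 1.5 Hz delta trains in N2/N3 over a
#'   theta and beta noise background, sub-slow-wave activity in N1, theta in
#'   REM and alpha in wake. The amplitudes and densities were chosen so a
#'   simulated night summarizes to NREM SO% near 26, delta% in the high 30s,
#'   SO-slope near 95 uV/s and delta-slope near 131 uV/s, the typical values
#'   reported for older adults with sleep apnoea.
default_components <- function() {
  list(
    list(stage = "N3", mode = "sinusoid_train", amplitude = 24, frequency = 0.7,
         density = 7, cycles = 2),
    list(stage = "N3", mode = "sinusoid_train", amplitude = 16, frequency = 1.5,
         density = 34, cycles = 2),
    list(stage = "N3", mode = "bandlimited_noise", amplitude = 3, f_lo = 4, f_hi = 7.9),
    list(stage = "N3", mode = "bandlimited_noise", amplitude = 5, f_lo = 15, f_hi = 30),
    list(stage = "N2", mode = "sinusoid_train", amplitude = 18, frequency = 0.7,
         density = 6, cycles = 2),
    list(stage = "N2", mode = "sinusoid_train", amplitude = 14, frequency = 1.5,
         density = 24, cycles = 2),
    list(stage = "N2", mode = "bandlimited_noise", amplitude = 3, f_lo = 4, f_hi = 7.9),
    list(stage = "N2", mode = "bandlimited_noise", amplitude = 5, f_lo = 15, f_hi = 30),
    list(stage = "N1", mode = "bandlimited_noise", amplitude = 3, f_lo = 0.5, f_hi = 0.9),
    list(stage = "N1", mode = "bandlimited_noise", amplitude = 5, f_lo = 1, f_hi = 3),
    list(stage = "N1", mode = "bandlimited_noise", amplitude = 6, f_lo = 4, f_hi = 7.9),
    list(stage = "N1", mode = "bandlimited_noise", amplitude = 5, f_lo = 15, f_hi = 30),
    list(stage = "R", mode = "bandlimited_noise", amplitude = 5, f_lo = 4, f_hi = 7.9),
    list(stage = "R", mode = "bandlimited_noise", amplitude = 4, f_lo = 15, f_hi = 30),
    list(stage = "W", mode = "sinusoid", amplitude = 8, frequency = 10)
  )
}

band_of_freq <- function(f) {
  b <- band_definitions()
  hit <- which(f >= b$f_lo & f <= b$f_hi)
  if (length(hit) == 0) NA_character_ else as.character(b$band[hit[1]])
}

# 1/f^a noise via spectral shaping of white Gaussian noise, scaled to RMS.
pink_noise <- function(n, exponent, rms) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))                     # avoid DC blow-up
  shaped <- W / f^(exponent / 2)
  x <- Re(fft(shaped, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / sd(x)
}

bandlimited_noise <- function(n, fs, f_lo, f_hi, rms) {
  w <- rnorm(n)
  W <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                          # two-sided frequency
  W[f < f_lo | f > f_hi] <- 0
  x <- Re(fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) numeric(n) else x * rms / s
}

#' Synthesize a PSG recording with ground truth
#'
#' Generates Fz, Cz, A1, A2 channels (the reference channels carry no
#' signal, so the Fz-Cz and Fz-earlobe derivations both recover the
#' configured mixture), a matching hypnogram on the 30-s grid, and a ground
#' truth object: every injected slow-wave event with its analytic downslope
#' `4 * A * f`, plus the expected relative PSD per band per epoch for the
#' noise-free part of the mixture.
#'
#' @param spec A `psg_spec`.
#' @return List with `recording` (`psg_recording`), `hypnogram` (tibble), and
#'   `truth`: list with `events` (tibble: onset, duration, amplitude,
#'   frequency, cycles, stage, analytic_downslope) and `expected_rel_psd`
#'   (tibble: epoch_index, band, rel_psd; `NA` where undefined).
#' @export
synthesize_recording <- function(spec) {
  stopifnot(inherits(spec, "psg_spec"))
  withr::with_seed(spec$seed, synthesize_recording_impl(spec))
}

synthesize_recording_impl <- function(spec) {
  fs <- spec$fs
  stages <- rep(spec$stage_sequence$stage, spec$stage_sequence$n_epochs)
  n_epochs <- length(stages)
  n <- n_epochs * EPOCH_SEC * fs
  t <- (seq_len(n) - 1) / fs
  epoch_of <- rep(seq_len(n_epochs) - 1L, each = EPOCH_SEC * fs)
  x <- numeric(n)

  events <- list()
  # expected band power per epoch (uV^2), noise-free part
  bdef <- band_definitions()
  pow <- matrix(0, nrow = n_epochs, ncol = nrow(bdef),
                dimnames = list(NULL, as.character(bdef$band)))

  for (cm in spec$components) {
    in_stage <- stages == cm$stage
    if (!any(in_stage)) next
    idx <- which(epoch_of %in% (which(in_stage) - 1L))
    mode <- cm$mode
    if (mode == "sinusoid") {
      x[idx] <- x[idx] + cm$amplitude * sin(2 * pi * cm$frequency * t[idx])
      b <- band_of_freq(cm$frequency)
      if (!is.na(b)) pow[in_stage, b] <- pow[in_stage, b] + cm$amplitude^2 / 2
    } else if (mode == "bandlimited_noise") {
      x[idx] <- x[idx] + bandlimited_noise(length(idx), fs, cm$f_lo, cm$f_hi, cm$amplitude)
      # noise spans its band; power attributed to the band containing its center
      b <- band_of_freq((cm$f_lo + cm$f_hi) / 2)
      if (!is.na(b)) pow[in_stage, b] <- pow[in_stage, b] + cm$amplitude^2
    } else if (mode == "sinusoid_train") {
      cycles <- cm$cycles %||% 2
      ev_dur <- cycles / cm$frequency
      for (e in which(in_stage)) {
        n_ev <- stats::rpois(1, cm$density * EPOCH_SEC / 60)
        if (n_ev == 0) next
        slots <- seq(0.5, EPOCH_SEC - ev_dur - 0.5, by = ev_dur + 0.5)
        if (length(slots) == 0) next
        n_ev <- min(n_ev, length(slots))
        onsets <- (e - 1) * EPOCH_SEC + sort(sample(slots, n_ev))
        for (on in onsets) {
          sel <- which(t >= on & t < on + ev_dur)
          x[sel] <- x[sel] - cm$amplitude * sin(2 * pi * cm$frequency * (t[sel] - on))
          events[[length(events) + 1]] <- tibble(
            onset = on, duration = ev_dur, amplitude = cm$amplitude,
            frequency = cm$frequency, cycles = cycles, stage = cm$stage,
            analytic_downslope = 4 * cm$amplitude * cm$frequency
          )
        }
        b <- band_of_freq(cm$frequency)
        duty <- n_ev * ev_dur / EPOCH_SEC
        if (!is.na(b)) pow[e, b] <- pow[e, b] + duty * cm$amplitude^2 / 2
      }
    } else {
      abort(paste0("Unknown component mode: ", mode))
    }
  }

  if (spec$noise_floor$scale > 0) {
    x <- x + pink_noise(n, spec$noise_floor$exponent, spec$noise_floor$scale)
  }

  rec <- psg_recording(
    channels = list(Fz = x, Cz = numeric(n), A1 = numeric(n), A2 = numeric(n)),
    fs = fs
  )
  hyp <- hypnogram(stages, portion = spec$portion)
  ev <- if (length(events)) arrange(list_rbind(events), .data$onset) else
    tibble(onset = numeric(), duration = numeric(), amplitude = numeric(),
           frequency = numeric(), cycles = numeric(), stage = character(),
           analytic_downslope = numeric())
  tot <- rowSums(pow)
  rel <- 100 * pow / ifelse(tot > 0, tot, NA_real_)   # row-wise; NA when undefined
  exp_rel <- tibble(
    epoch_index = rep(seq_len(n_epochs) - 1L, times = nrow(bdef)),
    band = rep(bdef$band, each = n_epochs),
    rel_psd = as.vector(rel)
  )
  list(recording = rec, hypnogram = hyp,
       truth = list(events = ev, expected_rel_psd = exp_rel))
}
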
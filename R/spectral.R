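# Per-epoch band power on the spectral derivation (Fz-Cz). Seven bands,
# closed intervals as conventionally printed; the small gaps between bands
# (e.g. 0.9-1.0 Hz) belong to no band.

#' The seven analysis bands
#'
#' Slow oscillation (SO) 0.5-0.9, delta 1-3.9, theta 4-7.9, alpha 8-11.9,
#' sigma 12-14.9, beta 15-29.9 and low gamma 30-35 Hz. Band limits are closed
#' intervals; frequencies in the gaps between bands are assigned to none.
#'
#' @return Tibble with columns `band`, `f_lo`, `f_hi`.
#' @export
band_definitions <- function() {
  tibble(
    band = factor(c("SO", "delta", "theta", "alpha", "sigma", "beta", "low_gamma"),
                  levels = c("SO", "delta", "theta", "alpha", "sigma", "beta", "low_gamma")),
    f_lo = c(0.5, 1, 4, 8, 12, 15, 30),
    f_hi = c(0.9, 3.9, 7.9, 11.9, 14.9, 29.9, 35)
  )
}

#' Welch power spectral density
#'
#' Averaged modified periodogram over Hamming-tapered overlapping segments,
#' one-sided density normalization (so that the integral of the PSD over
#' frequency recovers signal power, including for pure tones).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param segment_sec Segment length in seconds (default 8; 0.125 Hz bins, so
#'   the sub-hertz SO band spans several bins and Hamming main-lobe leakage of
#'   slow-oscillation components stays inside the band).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return Tibble with `freq` (Hz) and `psd` (power per Hz, e.g. uV^2/Hz).
#' @export
welch_psd <- function(x, fs, segment_sec = 8, overlap = 0.5) {
  nper <- as.integer(round(segment_sec * fs))
  if (nper > length(x)) abort("Welch segment longer than the signal.")
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- as.numeric(signal::hamming(nper))
  norm <- fs * sum(w^2)
  acc <- numeric(nper %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w              # constant detrend per segment
    sp <- abs(fft(seg)[seq_along(acc)])^2 / norm
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC and (for even nper) Nyquist
  dbl <- rep(2, length(psd)); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[length(psd)] <- 1
  tibble(freq = (seq_along(psd) - 1) * fs / nper, psd = psd * dbl)
}

#' Absolute and relative band power for one 30-s epoch
#'
#' Integrates the PSD over each band's closed interval; relative power is the
#' band's share of the summed power over the seven bands, in percent (summing
#' to 100 per epoch).
#'
#' @param window Numeric vector of one 30-s epoch (already 0.5-35 Hz filtered).
#' @param fs Sampling rate in Hz.
#' @param bands Band table as from [band_definitions()].
#' @param segment_sec,overlap Welch parameters (see [welch_psd()]);
#'   `segment_sec = 30` with `overlap = 0` gives a single-taper periodogram.
#' @return Tibble, one row per band: `band`, `abs_power` (uV^2), `rel_psd`
#'   (%). For an all-zero window powers are 0 and `rel_psd` is `NA` (the
#'   relative split is undefined).
#' @export
epoch_band_powers <- function(window, fs, bands = band_definitions(),
                              segment_sec = 8, overlap = 0.5) {
  spec <- welch_psd(window, fs, segment_sec = segment_sec, overlap = overlap)
  df <- spec$freq[2] - spec$freq[1]
  eps <- df / 1e6
  abs_power <- map_dbl(seq_len(nrow(bands)), function(i) {
    sel <- spec$freq >= bands$f_lo[i] - eps & spec$freq <= bands$f_hi[i] + eps
    sum(spec$psd[sel]) * df
  })
  tot <- sum(abs_power)
  tibble(
    band = bands$band,
    abs_power = abs_power,
    rel_psd = if (tot > 0) 100 * abs_power / tot else NA_real_
  )
}

#' Per-epoch band features for a whole recording
#'
#' Slices the spectral derivation on the hypnogram's 30-s grid and computes
#' band powers per epoch. Artifact epochs are carried with `NA` powers.
#'
#' The band integration itself restricts the analysis to 0.5-35 Hz, so by
#' default no bandpass pre-filter is applied: the 2000-tap design used for
#' slow-wave detection has its transition band inside the slow-oscillation
#' band (0.5-0.9 Hz) and would attenuate SO power by roughly a quarter,
#' biasing the relative split. Set `prefilter = TRUE` to filter the
#' continuous signal first (filtering is done once over the whole recording
#' to avoid per-epoch edge transients).
#'
#' @param rec A `psg_recording`.
#' @param hyp Hypnogram tibble.
#' @param positive,references Spectral derivation (default Fz-Cz).
#' @param segment_sec,overlap Welch parameters.
#' @param prefilter Apply the 0.5-35 Hz zero-phase bandpass before the PSD
#'   (default `FALSE`; see Details).
#' @param reject_artifacts Apply [flag_artifacts()] before computing (default
#'   `TRUE`); externally supplied flags are kept either way.
#' @return Long tibble: `epoch_index`, `stage`, `portion`, `artifact`,
#'   `band`, `abs_power`, `rel_psd`.
#' @export
compute_band_features <- function(rec, hyp, positive = "Fz", references = "Cz",
                                  segment_sec = 8, overlap = 0.5,
                                  prefilter = FALSE, reject_artifacts = TRUE) {
  x <- make_derivation(rec, positive, references)
  xf <- if (prefilter) filter_zero_phase(x, design_bandpass(rec$fs)) else x
  ep <- epoch_slices(rec, hyp, signal = xf)
  if (reject_artifacts) {
    raw_ep <- epoch_slices(rec, hyp, signal = x)
    ep$artifact <- flag_artifacts(raw_ep, rec$fs)$artifact
  }
  bands <- band_definitions()
  rows <- map(seq_len(nrow(ep)), function(i) {
    meta <- ep[i, c("epoch_index", "stage", "portion", "artifact")]
    if (ep$artifact[i]) {
      bp <- tibble(band = bands$band, abs_power = NA_real_, rel_psd = NA_real_)
    } else {
      bp <- epoch_band_powers(ep$samples[[i]], rec$fs,
                              segment_sec = segment_sec, overlap = overlap)
    }
    cbind(meta[rep(1, nrow(bp)), ], bp)
  })
  as_tibble(list_rbind(rows))
}

#' Summarize relative PSD over NREM (or N3-only) epochs
#'
#' Unweighted mean of per-epoch relative PSD per band over eligible,
#' non-artifact epochs of the requested study portion. The N3-only selection
#' requires at least `min_n3_epochs` eligible N3 epochs (default 30, i.e.
#' 15 min of N3 representation); otherwise the summary is returned missing
#' with a reason code.
#'
#' @param features Per-epoch long tibble from [compute_band_features()].
#' @param selection `"nrem"` (stages N1-N3) or `"n3"`.
#' @param portion `"diagnostic"` or `"titration"`.
#' @param min_n3_epochs Minimum eligible N3 epochs for the N3-only summary.
#' @return Tibble, one row per band: `band`, `mean_rel_psd`, `n_epochs`,
#'   `selection`, `portion`, `reason` (`NA` when defined).
#' @export
summarize_relative_psd <- function(features, selection = c("nrem", "n3"),
                                   portion = "diagnostic", min_n3_epochs = 30) {
  selection <- match.arg(selection)
  stages <- if (selection == "nrem") NREM_STAGES else "N3"
  elig <- features |>
    filter(.data$portion == !!portion, .data$stage %in% stages,
           !.data$artifact, !is.na(.data$rel_psd))
  n_epochs <- length(unique(elig$epoch_index))
  missing_reason <- NA_character_
  if (n_epochs == 0) missing_reason <- "no eligible epochs"
  if (selection == "n3" && n_epochs < min_n3_epochs) missing_reason <- "insufficient N3"
  if (!is.na(missing_reason)) {
    return(tibble(band = band_definitions()$band, mean_rel_psd = NA_real_,
                  n_epochs = n_epochs, selection = selection, portion = portion,
                  reason = missing_reason))
  }
  elig |>
    group_by(.data$band) |>
    summarise(mean_rel_psd = mean(.data$rel_psd), .groups = "drop") |>
    mutate(n_epochs = n_epochs, selection = selection, portion = portion,
           reason = NA_character_)
}
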
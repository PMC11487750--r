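# Negative half-wave detection on the smoothed 0.5-35 Hz Fz-earlobe signal.
# Waves are classed slow oscillation (SO) vs delta by the separation of
# their bounding descending zero-crossings (full-wave period criterion by
# default: 1.1-2 s <-> 0.5-0.91 Hz, 0.25-1.0 s <-> 1-4 Hz, matching the
# spectral bands). The downslope is the zero-crossing-to-trough amplitude
# divided by the elapsed time.

SO_SEP <- c(1.1, 2)
DELTA_SEP <- c(0.25, 1.0)

# Linearly interpolated descending (pos->neg) and ascending crossing times (s).
zero_crossings <- function(x, fs) {
  n <- length(x)
  a <- x[-n]; b <- x[-1]
  desc <- which(a > 0 & b <= 0)
  asc <- which(a <= 0 & b > 0)
  interp <- function(i) (i - 1 + a[i] / (a[i] - b[i])) / fs
  list(desc = interp(desc), asc = interp(asc),
       desc_idx = desc, asc_idx = asc)
}

#' Detect slow-wave negative half-waves
#'
#' Scans a smoothed, bandpass-filtered signal for descending zero-crossings,
#' classifies each candidate wave by the separation of its bounding crossings,
#' locates the trough (global minimum between the crossings, earliest sample
#' on ties) and computes the downslope. Candidates with troughs above the
#' amplitude threshold are discarded.
#'
#' @param x Numeric signal: 0.5-35 Hz filtered and 50-ms smoothed (see
#'   [filter_zero_phase()], [smooth_moving_average()]).
#' @param fs Sampling rate in Hz.
#' @param criterion `"period"` (default): the bounding crossings are two
#'   successive descending zero-crossings, so the separation is the full-wave
#'   period; `"halfwave"`: the separation is the descending-to-ascending
#'   crossing interval of the negative half-wave itself.
#' @param amp_threshold Trough threshold in microvolts (default -5): waves
#'   with troughs above (less negative than) it are discarded.
#' @param t_offset Seconds added to all returned times (for signals that do
#'   not start at recording time 0).
#' @return Tibble, one row per detected wave: `band` ("SO"/"delta"),
#'   `t_zero_cross`, `t_trough`, `trough_amp` (uV), `separation` (s),
#'   `downslope` (uV/s, positive magnitude). Empty for signals shorter than
#'   2 s.
#' @export
detect_halfwaves <- function(x, fs, criterion = c("period", "halfwave"),
                             amp_threshold = -5, t_offset = 0) {
  criterion <- match.arg(criterion)
  empty <- tibble(band = character(), t_zero_cross = numeric(),
                  t_trough = numeric(), trough_amp = numeric(),
                  separation = numeric(), downslope = numeric())
  if (length(x) < 2 * fs) return(empty)
  zc <- zero_crossings(x, fs)
  if (length(zc$desc) < 2) return(empty)

  if (criterion == "period") {
    k <- seq_len(length(zc$desc) - 1L)
    t0 <- zc$desc[k]; t1 <- zc$desc[k + 1L]
    i0 <- zc$desc_idx[k] + 1L; i1 <- zc$desc_idx[k + 1L]
  } else {
    # each descending crossing paired with the next ascending crossing
    nxt <- findInterval(zc$desc, zc$asc) + 1L
    ok <- nxt <= length(zc$asc)
    t0 <- zc$desc[ok]; t1 <- zc$asc[nxt[ok]]
    i0 <- zc$desc_idx[ok] + 1L; i1 <- zc$asc_idx[nxt[ok]]
  }
  sep <- t1 - t0
  band <- ifelse(sep >= SO_SEP[1] & sep <= SO_SEP[2], "SO",
                 ifelse(sep >= DELTA_SEP[1] & sep <= DELTA_SEP[2], "delta", NA))
  keep <- which(!is.na(band))
  if (length(keep) == 0) return(empty)

  rows <- map(keep, function(j) {
    seg <- x[i0[j]:i1[j]]
    rel <- which.min(seg)                       # earliest index on exact ties
    trough_amp <- seg[rel]
    t_trough <- (i0[j] + rel - 2) / fs
    tibble(band = band[j], t_zero_cross = t0[j], t_trough = t_trough,
           trough_amp = trough_amp, separation = sep[j],
           downslope = abs(trough_amp) / (t_trough - t0[j]))
  })
  hw <- list_rbind(rows)
  hw <- hw[hw$trough_amp <= amp_threshold, , drop = FALSE]
  hw$t_zero_cross <- hw$t_zero_cross + t_offset
  hw$t_trough <- hw$t_trough + t_offset
  as_tibble(hw)
}

#' Detect slow waves on a recording's slope derivation
#'
#' Full per-recording path: builds the slope derivation (Fz referenced to the
#' earlobe average by default), bandpass-filters with zero phase, applies the
#' 50-ms moving average, detects half-waves, and tags each wave with the
#' hypnogram epoch containing its trough.
#'
#' @param rec A `psg_recording`.
#' @param hyp Hypnogram tibble.
#' @param positive,references Slope derivation (default Fz vs mean of A1, A2).
#' @param criterion,amp_threshold See [detect_halfwaves()].
#' @param reject_artifacts Flag artifact epochs from the raw derivation
#'   (default `TRUE`).
#' @return Tibble of half-waves with `epoch_index`, `stage`, `portion`,
#'   `artifact` joined on.
#' @export
compute_slope_features <- function(rec, hyp, positive = "Fz",
                                   references = c("A1", "A2"),
                                   criterion = "period", amp_threshold = -5,
                                   reject_artifacts = TRUE) {
  hyp <- validate_hypnogram(hyp)
  x <- make_derivation(rec, positive, references)
  h <- design_bandpass(rec$fs)
  xs <- smooth_moving_average(filter_zero_phase(x, h), rec$fs)
  hw <- detect_halfwaves(xs, rec$fs, criterion = criterion,
                         amp_threshold = amp_threshold)
  hyp2 <- hyp
  if (reject_artifacts) {
    raw_ep <- epoch_slices(rec, hyp, signal = x)
    hyp2$artifact <- flag_artifacts(raw_ep, rec$fs)$artifact
  }
  hw$epoch_index <- as.integer(floor(hw$t_trough / EPOCH_SEC))
  hw |>
    inner_join(hyp2, by = "epoch_index") |>
    as_tibble()
}

#' Summarize slow-wave downslopes over NREM epochs
#'
#' Two-step pooling: slopes are averaged within each 30-s epoch per band,
#' then the per-epoch means are averaged (unweighted) across eligible NREM
#' epochs that contain at least one detection in that band. Detection-weighted
#' pooling is available via `weight_by_count`.
#'
#' @param halfwaves Output of [compute_slope_features()] (epoch-tagged waves).
#' @param portion Study portion to summarize (default "diagnostic").
#' @param stages Stages considered (default NREM: N1, N2, N3).
#' @param weight_by_count If `TRUE`, pool all detections directly instead of
#'   averaging epoch means.
#' @return Tibble, one row per band: `band`, `mean_slope` (uV/s), `n_epochs`,
#'   `n_detections`, `portion`, `reason` (`NA` when defined; a band with no
#'   detections in any eligible epoch is reported missing).
#' @export
summarize_slopes <- function(halfwaves, portion = "diagnostic",
                             stages = NREM_STAGES, weight_by_count = FALSE) {
  elig <- halfwaves |>
    filter(.data$portion == !!portion, .data$stage %in% stages, !.data$artifact)
  out <- map(c("SO", "delta"), function(b) {
    bw <- elig[elig$band == b, , drop = FALSE]
    if (nrow(bw) == 0) {
      return(tibble(band = b, mean_slope = NA_real_, n_epochs = 0L,
                    n_detections = 0L, portion = portion,
                    reason = "no detections in eligible epochs"))
    }
    per_epoch <- bw |>
      group_by(.data$epoch_index) |>
      summarise(m = mean(.data$downslope), k = n(), .groups = "drop")
    mean_slope <- if (weight_by_count) mean(bw$downslope) else mean(per_epoch$m)
    tibble(band = b, mean_slope = mean_slope, n_epochs = nrow(per_epoch),
           n_detections = nrow(bw), portion = portion, reason = NA_character_)
  })
  list_rbind(out)
}
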
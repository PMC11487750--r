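#' Participant-level slow-wave features from one recording
#'
#' End-to-end extraction: relative band power per epoch on the spectral
#' derivation (Fz-Cz), half-wave downslopes on the slope derivation
#' (Fz-earlobe average), summarized over NREM epochs of each requested study
#' portion. These are the per-participant exposures used in the association
#' models: mean SO%, mean delta%, mean SO-slope, mean delta-slope and their
#' ratios.
#'
#' @param rec A `psg_recording`.
#' @param hyp Hypnogram tibble.
#' @param portions Study portions to summarize (default both present in the
#'   hypnogram).
#' @param selection `"nrem"` or `"n3"` epoch selection for the spectral
#'   summary (slopes always pool NREM epochs with detections; for `"n3"` the
#'   slope summary is restricted to N3 likewise).
#' @param spectral_derivation,slope_derivation Lists with `positive` and
#'   `references` for the two derivations.
#' @param segment_sec Welch segment length (s).
#' @return Tibble, one row per portion: `portion`, `selection`, `so_pct`,
#'   `delta_pct`, `so_slope`, `delta_slope`, `so_delta_pct_ratio`,
#'   `so_delta_slope_ratio`, `n_epochs_psd`, `n_detections_so`,
#'   `n_detections_delta`.
#' @export
extract_swa_features <- function(rec, hyp,
                                 portions = NULL,
                                 selection = "nrem",
                                 spectral_derivation = list(positive = "Fz", references = "Cz"),
                                 slope_derivation = list(positive = "Fz", references = c("A1", "A2")),
                                 segment_sec = 8) {
  hyp <- validate_hypnogram(hyp)
  portions <- portions %||% unique(hyp$portion)
  bf <- compute_band_features(rec, hyp,
                              positive = spectral_derivation$positive,
                              references = spectral_derivation$references,
                              segment_sec = segment_sec)
  hw <- compute_slope_features(rec, hyp,
                               positive = slope_derivation$positive,
                               references = slope_derivation$references)
  stages <- if (selection == "nrem") NREM_STAGES else "N3"
  rows <- map(portions, function(p) {
    psd <- summarize_relative_psd(bf, selection = selection, portion = p)
    sl <- summarize_slopes(hw, portion = p, stages = stages)
    pick <- function(tab, b, col) {
      v <- tab[[col]][tab$band == b]
      if (length(v) == 0) NA_real_ else v
    }
    so_pct <- pick(psd, "SO", "mean_rel_psd")
    delta_pct <- pick(psd, "delta", "mean_rel_psd")
    so_slope <- pick(sl, "SO", "mean_slope")
    delta_slope <- pick(sl, "delta", "mean_slope")
    tibble(
      portion = p, selection = selection,
      so_pct = so_pct, delta_pct = delta_pct,
      so_slope = so_slope, delta_slope = delta_slope,
      so_delta_pct_ratio = so_pct / delta_pct,
      so_delta_slope_ratio = so_slope / delta_slope,
      n_epochs_psd = psd$n_epochs[1],
      n_detections_so = pick(sl, "SO", "n_detections"),
      n_detections_delta = pick(sl, "delta", "n_detections")
    )
  })
  list_rbind(rows)
}
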
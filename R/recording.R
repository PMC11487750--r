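#' Construct a polysomnographic recording object
#'
#' Container for multichannel EEG in physical units (microvolts) on one
#' sampling grid. All channels must have equal length.
#'
#' @param channels Named list of numeric vectors (samples in microvolts).
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Recording start (POSIXct); defaults to an arbitrary epoch.
#' @param units Optional named character of physical dimensions per channel.
#' @return A `psg_recording` object.
#' @export
psg_recording <- function(channels, fs, start_time = NULL, units = NULL) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a named list of numeric vectors.")
  }
  lens <- lengths(channels)
  if (length(unique(lens)) != 1) abort("All channels must have the same length.")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("`fs` must be a positive scalar.")
  new_psg_recording(channels, fs, start_time %||% as.POSIXct("2000-01-01", tz = "UTC"),
                    units %||% setNames(rep("uV", length(channels)), names(channels)))
}

new_psg_recording <- function(channels, fs, start_time, units) {
  structure(list(channels = channels, fs = fs, start_time = start_time,
                 units = units),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<psg_recording> %d channel(s), %g Hz, %.1f s (%s)\n",
              length(x$channels), x$fs, n / x$fs,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Referential or linked-reference derivation
#'
#' Builds a single-channel signal as the named electrode minus the mean of
#' one or more reference electrodes, e.g. `Fz-Cz` or Fz referenced to the
#' earlobe average (A1 + A2)/2 as used for slow-wave slope measurement.
#'
#' @param rec A `psg_recording`.
#' @param positive Label of the exploring electrode.
#' @param references Character vector of reference labels (averaged then
#'   subtracted). Must be non-empty.
#' @return Numeric vector, same length as the recording, in microvolts.
#' @examples
#' rec <- psg_recording(list(Fz = c(10, 10), A1 = c(2, 2), A2 = c(4, 4)), fs = 1)
#' make_derivation(rec, "Fz", c("A1", "A2"))   # 7 7
#' @export
make_derivation <- function(rec, positive, references) {
  stopifnot(inherits(rec, "psg_recording"))
  if (length(references) == 0) abort("`references` must name at least one channel.")
  labs <- c(positive, references)
  missing <- setdiff(labs, names(rec$channels))
  if (length(missing) > 0) {
    abort(paste0("Channel(s) not in recording: ", paste(missing, collapse = ", "),
                 ". Available: ", paste(names(rec$channels), collapse = ", ")))
  }
  ref <- Reduce(`+`, rec$channels[references]) / length(references)
  rec$channels[[positive]] - ref
}

#' Parse a derivation string
#'
#' Accepts `"Fz-Cz"` (single reference) or `"Fz:(A1,A2)"` (averaged
#' references) and returns the `positive`/`references` pair.
#'
#' @param spec Character scalar.
#' @return List with `positive` and `references`.
#' @export
parse_derivation <- function(spec) {
  spec <- trimws(spec)
  if (grepl(":", spec, fixed = TRUE)) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    refs <- gsub("[()\\s]", "", parts[2])
    refs <- strsplit(refs, ",", fixed = TRUE)[[1]]
  } else {
    parts <- strsplit(spec, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2) abort(paste0("Cannot parse derivation: ", spec))
    refs <- parts[2]
  }
  list(positive = trimws(parts[1]), references = trimws(refs))
}

#' Slice a derived signal into stage-labelled 30-s epochs
#'
#' Aligns a hypnogram's 30-s epoch grid (anchored at recording start, 0-based
#' indices, half-open windows) to the recording and returns one row per epoch
#' with its sample window. A trailing partial epoch in the recording is
#' discarded with a warning; artifact-flagged epochs are carried through with
#' their flag, never silently dropped.
#'
#' @param rec A `psg_recording`.
#' @param hypnogram Hypnogram tibble (see [read_hypnogram()]): columns
#'   `epoch_index`, `stage`, `portion`, `artifact`.
#' @param positive,references Derivation passed to [make_derivation()]; or
#'   give `signal` directly.
#' @param signal Optional pre-computed single-channel signal (overrides the
#'   derivation arguments).
#' @return Tibble with columns `epoch_index`, `stage`, `portion`, `artifact`,
#'   and a list-column `samples` of 30 * fs numeric windows.
#' @export
epoch_slices <- function(rec, hypnogram, positive = NULL, references = NULL,
                         signal = NULL) {
  stopifnot(inherits(rec, "psg_recording"))
  hypnogram <- validate_hypnogram(hypnogram)
  x <- signal %||% make_derivation(rec, positive, references)
  fs <- rec$fs
  n_per <- EPOCH_SEC * fs
  if (abs(n_per - round(n_per)) > 1e-9) abort("30 s is not a whole number of samples at this fs.")
  n_per <- as.integer(round(n_per))
  n_full <- length(x) %/% n_per
  if (length(x) %% n_per != 0) {
    warn(sprintf("Recording has a trailing partial epoch (%.1f s); discarded.",
                 (length(x) %% n_per) / fs))
  }
  if (nrow(hypnogram) > n_full) {
    abort(sprintf("Hypnogram covers %d epochs but recording holds only %d full epochs.",
                  nrow(hypnogram), n_full))
  }
  wins <- map(hypnogram$epoch_index, function(i) x[i * n_per + seq_len(n_per)])
  tibble(
    epoch_index = hypnogram$epoch_index,
    stage = hypnogram$stage,
    portion = hypnogram$portion,
    artifact = hypnogram$artifact,
    samples = wins
  )
}

#' Flag artifact epochs by amplitude and flat-line rules
#'
#' Marks an epoch as artifact if any sample exceeds `amp_limit` in absolute
#' value or the signal stays constant for longer than `flat_sec` seconds.
#' External flags already present are kept (logical OR).
#'
#' @param epochs Output of [epoch_slices()].
#' @param fs Sampling rate in Hz.
#' @param amp_limit Amplitude bound in microvolts (default 250).
#' @param flat_sec Maximum tolerated run of constant signal in seconds
#'   (default 5).
#' @return `epochs` with the `artifact` column updated.
#' @export
flag_artifacts <- function(epochs, fs, amp_limit = 250, flat_sec = 5) {
  auto <- map_dbl(epochs$samples, function(w) {
    if (any(abs(w) > amp_limit)) return(1)
    r <- rle(w)
    if (any(r$lengths > flat_sec * fs)) return(1)
    0
  })
  epochs$artifact <- epochs$artifact | (auto > 0)
  epochs
}
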
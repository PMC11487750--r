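# EDF (European Data Format) 16-bit I/O.
#
# The format is a fixed-width ASCII header (256 bytes + 256 per signal)
# followed by data records of little-endian int16 samples, one block per
# signal per record. Physical values are recovered by the affine map
# defined by the (physical, digital) min/max header fields.

#' Read an EDF recording
#'
#' Reads a 16-bit EDF/EDF+ continuous recording and returns all (or selected)
#' signals in physical units. Polysomnographic exports store EEG in microvolts;
#' the physical dimension field is carried through per channel.
#'
#' @param path Path to an `.edf` file.
#' @param channels Optional character vector of channel labels to keep.
#'   Unknown labels raise an error listing the labels present in the file.
#' @return A `psg_recording`: a list with `channels` (named list of numeric
#'   sample vectors, microvolts), `fs` (sampling rate in Hz, per the header),
#'   `start_time` (POSIXct) and `units` (named character).
#' @details All retained channels must share one sampling rate; recordings
#'   where EEG channels are stored at different rates should be read
#'   per-channel and resampled explicitly (see [resample_signal()]). The
#'   header sampling rate is returned as-is even when a downstream analysis
#'   expects 500 Hz; resampling is a separate, explicit step.
#' @seealso [write_edf()], [make_derivation()], [epoch_slices()]
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) abort(paste0("EDF file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr_chr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_chr(8)
  if (!identical(version, "0")) abort("Corrupt EDF header: version field is not '0'.")
  hdr_chr(80); hdr_chr(80)                      # patient, recording id
  startdate <- hdr_chr(8); starttime <- hdr_chr(8)
  header_bytes <- as.integer(hdr_chr(8))
  hdr_chr(44)                                   # reserved
  n_records <- as.integer(hdr_chr(8))
  record_dur <- as.numeric(hdr_chr(8))
  ns <- as.integer(hdr_chr(4))
  if (is.na(ns) || ns < 1) abort("Corrupt EDF header: invalid signal count.")

  field <- function(width) vapply(seq_len(ns), function(i) hdr_chr(width), character(1))
  labels <- field(16)
  field(80)                                     # transducer
  physdim <- field(8)
  physmin <- as.numeric(field(8)); physmax <- as.numeric(field(8))
  digmin  <- as.numeric(field(8)); digmax  <- as.numeric(field(8))
  field(80)                                     # prefilter
  spr <- as.integer(field(8))                   # samples per record
  field(32)                                     # reserved
  if (anyNA(c(physmin, physmax, digmin, digmax, spr, n_records, record_dur))) {
    abort("Corrupt EDF header: non-numeric scaling fields.")
  }

  keep <- seq_len(ns)
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing) > 0) {
      abort(paste0(
        "Channel(s) not found in EDF: ", paste(missing, collapse = ", "),
        ". Available: ", paste(labels, collapse = ", ")
      ))
    }
    keep <- match(channels, labels)
  }

  seek(con, header_bytes)
  raw_all <- readBin(con, "integer", n = n_records * sum(spr), size = 2,
                     signed = TRUE, endian = "little")
  if (length(raw_all) < n_records * sum(spr)) abort("Truncated EDF data section.")

  offsets <- c(0L, cumsum(spr))
  rec_len <- sum(spr)
  gain <- (physmax - physmin) / (digmax - digmin)
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    idx <- as.vector(outer(seq_len(spr[i]) + offsets[i], (seq_len(n_records) - 1L) * rec_len, "+"))
    dig <- raw_all[idx]
    out[[j]] <- physmin[i] + gain[i] * (dig - digmin[i])
  }
  names(out) <- labels[keep]

  fs <- unique(spr[keep] / record_dur)
  if (length(fs) > 1) {
    abort("Selected channels have different sampling rates; read them separately.")
  }
  start_time <- edf_start_posix(startdate, starttime)
  new_psg_recording(channels = out, fs = fs, start_time = start_time,
                    units = setNames(physdim[keep], labels[keep]))
}

edf_start_posix <- function(startdate, starttime) {
  dt <- try(as.POSIXct(paste(startdate, starttime), format = "%d.%m.%y %H.%M.%S",
                       tz = "UTC"), silent = TRUE)
  if (inherits(dt, "try-error") || is.na(dt)) as.POSIXct("2000-01-01", tz = "UTC") else dt
}

#' Write a recording as 16-bit EDF
#'
#' Quantizes each channel to the full int16 range with per-channel physical
#' scaling, so the round trip `write_edf()` then [read_edf()] agrees with the
#' input to within one digital quantization step.
#'
#' @param rec A `psg_recording` (see [psg_recording()]).
#' @param path Output path.
#' @param record_dur Data-record duration in seconds (default 1); `fs *
#'   record_dur` must be an integer. Signals are zero-padded to a whole number
#'   of records (with a warning) because EDF stores complete records only.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_dur = 1) {
  stopifnot(inherits(rec, "psg_recording"))
  fs <- rec$fs
  spr <- fs * record_dur
  if (abs(spr - round(spr)) > 1e-9) abort("fs * record_dur must be an integer.")
  spr <- as.integer(round(spr))
  ns <- length(rec$channels)
  n <- length(rec$channels[[1]])
  n_records <- ceiling(n / spr)
  if (n_records * spr != n) {
    warn("Signal length is not a whole number of EDF records; zero-padding the tail.")
  }

  physmin <- physmax <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- rec$channels[[i]]
    r <- range(x)
    if (diff(r) == 0) r <- r + c(-1, 1)         # avoid zero-width physical range
    physmin[i] <- r[1]; physmax[i] <- r[2]
    g <- (r[2] - r[1]) / 65535
    d <- as.integer(round((x - r[1]) / g) - 32768L)
    length(d) <- n_records * spr
    d[is.na(d)] <- as.integer(round((0 - r[1]) / g) - 32768L)
    dig[[i]] <- d
  }

  pad <- function(x, width) {
    x <- substr(as.character(x), 1, width)
    formatC(x, width = width, flag = "-")
  }
  fnum <- function(x, width) pad(formatC(x, format = "g", digits = 7), width)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s) writeBin(charToRaw(paste0(s, collapse = "")), con)
  st <- rec$start_time %||% as.POSIXct("2000-01-01", tz = "UTC")
  wr(pad("0", 8))
  wr(pad("X X X X", 80)); wr(pad("Startdate X X X X", 80))
  wr(pad(format(st, "%d.%m.%y"), 8)); wr(pad(format(st, "%H.%M.%S"), 8))
  wr(pad(256 * (ns + 1), 8)); wr(pad("", 44))
  wr(pad(n_records, 8)); wr(fnum(record_dur, 8)); wr(pad(ns, 4))
  units <- rec$units %||% setNames(rep("uV", ns), names(rec$channels))
  wr(vapply(names(rec$channels), pad, "", width = 16))
  wr(vapply(seq_len(ns), function(i) pad("", 80), ""))
  wr(vapply(names(rec$channels), function(ch) pad(units[[ch]] %||% "uV", 8), ""))
  wr(vapply(physmin, fnum, "", width = 8))
  wr(vapply(physmax, fnum, "", width = 8))
  wr(vapply(seq_len(ns), function(i) pad(-32768L, 8), ""))
  wr(vapply(seq_len(ns), function(i) pad(32767L, 8), ""))
  wr(vapply(seq_len(ns), function(i) pad("", 80), ""))
  wr(vapply(seq_len(ns), function(i) pad(spr, 8), ""))
  wr(vapply(seq_len(ns), function(i) pad("", 32), ""))

  mat <- matrix(0L, nrow = spr * ns, ncol = n_records)
  for (i in seq_len(ns)) {
    mat[(i - 1L) * spr + seq_len(spr), ] <- matrix(dig[[i]], nrow = spr)
  }
  writeBin(as.integer(mat), con, size = 2, endian = "little")
  invisible(path)
}
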
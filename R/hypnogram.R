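# Hypnogram: per-30-s-epoch stage labels with study-portion flags.
# Dialect: a TSV with columns epoch_index (0-based), stage (W/N1/N2/N3/R),
# portion (diagnostic/titration), artifact (logical). Split-night studies
# carry the diagnostic portion first, then the PAP titration portion.

#' Build a hypnogram tibble
#'
#' @param stage Character vector of stages (`W`, `N1`, `N2`, `N3`, `R`), one
#'   per 30-s epoch in temporal order.
#' @param portion `"diagnostic"` or `"titration"` per epoch (scalar recycled).
#' @param artifact Logical per epoch (scalar recycled).
#' @param epoch_index Optional 0-based indices; defaults to `0:(n-1)` and must
#'   be contiguous from 0.
#' @return A validated hypnogram tibble.
#' @export
hypnogram <- function(stage, portion = "diagnostic", artifact = FALSE,
                      epoch_index = NULL) {
  n <- length(stage)
  h <- tibble(
    epoch_index = epoch_index %||% (seq_len(n) - 1L),
    stage = as.character(stage),
    portion = rep_len(as.character(portion), n),
    artifact = rep_len(as.logical(artifact), n)
  )
  validate_hypnogram(h)
}

validate_hypnogram <- function(h) {
  h <- as_tibble(h)
  need <- c("epoch_index", "stage", "portion", "artifact")
  miss <- setdiff(need, names(h))
  if (length(miss) > 0) abort(paste0("Hypnogram lacks column(s): ", paste(miss, collapse = ", ")))
  h$epoch_index <- as.integer(h$epoch_index)
  if (nrow(h) > 0 && !identical(h$epoch_index, seq_len(nrow(h)) - 1L)) {
    abort("Hypnogram epoch_index must be contiguous from 0.")
  }
  bad <- setdiff(unique(h$stage), STAGES)
  if (length(bad) > 0) abort(paste0("Unknown sleep stage(s): ", paste(bad, collapse = ", ")))
  badp <- setdiff(unique(h$portion), PORTIONS)
  if (length(badp) > 0) abort(paste0("Unknown portion label(s): ", paste(badp, collapse = ", ")))
  h$artifact <- as.logical(h$artifact)
  h
}

#' Read / write the hypnogram TSV dialect
#'
#' @param path File path.
#' @return `read_hypnogram()`: a validated hypnogram tibble.
#' @export
read_hypnogram <- function(path) {
  h <- readr::read_tsv(path, col_types = readr::cols(
    epoch_index = readr::col_integer(),
    stage = readr::col_character(),
    portion = readr::col_character(),
    artifact = readr::col_logical()
  ))
  validate_hypnogram(h)
}

#' @rdname read_hypnogram
#' @param h Hypnogram tibble.
#' @export
write_hypnogram <- function(h, path) {
  readr::write_tsv(validate_hypnogram(h), path)
  invisible(path)
}

#' Map stage annotations onto the 30-s epoch grid
#'
#' Converts an annotation table of timed stage labels (for instance extracted
#' from EDF+ annotations by any reader) to the package's epoch-grid hypnogram
#' by majority stage per 30-s window, ties broken by the earlier-starting
#' annotation.
#'
#' @param annotations Data frame with columns `onset` (s from recording
#'   start), `duration` (s) and `stage`.
#' @param n_epochs Number of 30-s epochs to cover.
#' @param portion,artifact Passed through to [hypnogram()].
#' @return Hypnogram tibble.
#' @export
hypnogram_from_annotations <- function(annotations, n_epochs,
                                       portion = "diagnostic", artifact = FALSE) {
  a <- as_tibble(annotations)
  stopifnot(all(c("onset", "duration", "stage") %in% names(a)))
  a <- arrange(a, .data$onset)
  stages <- vapply(seq_len(n_epochs) - 1L, function(i) {
    lo <- i * EPOCH_SEC; hi <- lo + EPOCH_SEC
    ov <- pmin(a$onset + a$duration, hi) - pmax(a$onset, lo)
    keep <- ov > 0
    if (!any(keep)) return(NA_character_)
    cover <- tapply(ov[keep], a$stage[keep], sum)
    names(cover)[which.max(cover)]           # ties: tapply keeps first label order
  }, character(1))
  if (anyNA(stages)) abort("Annotation gaps: some 30-s epochs have no stage label.")
  hypnogram(stages, portion = portion, artifact = artifact)
}
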
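# PiB-PET aggregation: global SUVR from the six amyloid-susceptible ROIs,
# annualized log-scale accumulation, centiloid conversion and baseline
# amyloid-positivity classification.

PIB_ROIS <- c("orbitofrontal", "prefrontal", "anterior_cingulate",
              "posterior_cingulate_precuneus", "parietal", "temporal")

PIB_POS_CUTOFF <- 1.48

#' Global PiB SUVR from regional values
#'
#' Weighted mean over the six ROIs (orbitofrontal, pre-frontal,
#' anterior/mid-cingulate, posterior cingulate/precuneus, parietal,
#' temporal); unweighted when no weights are supplied.
#'
#' @param suvr Named numeric of regional SUVRs; all six ROIs must be present
#'   (names as in `swamyloid:::PIB_ROIS`).
#' @param weights Optional numeric weights, same names/order.
#' @return Global SUVR (scalar).
#' @export
global_suvr <- function(suvr, weights = NULL) {
  missing <- setdiff(PIB_ROIS, names(suvr))
  if (length(missing) > 0) {
    abort(paste0("Missing ROI SUVR(s): ", paste(missing, collapse = ", ")))
  }
  v <- as.numeric(suvr[PIB_ROIS])
  if (any(v <= 0)) abort("SUVRs must be positive.")
  if (is.null(weights)) return(mean(v))
  w <- if (!is.null(names(weights))) as.numeric(weights[PIB_ROIS]) else as.numeric(weights)
  sum(w * v) / sum(w)
}

#' Annualized log-scale SUVR change
#'
#' `(ln s2 - ln s1) / interval`: the difference of the log-transformed
#' follow-up and baseline SUVRs divided by the scan interval in years.
#' Antisymmetric in the two scans and invariant to rescaling both by a
#' common factor.
#'
#' @param s1,s2 Baseline and follow-up SUVR (> 0).
#' @param interval Years between scans (> 0).
#' @return Change in log-SUVR per year.
#' @examples
#' annualized_log_change(1.44, 1.48, 2.7)  # 0.010148
#' @export
annualized_log_change <- function(s1, s2, interval) {
  if (any(s1 <= 0) || any(s2 <= 0)) abort("SUVRs must be positive.")
  if (any(interval <= 0)) abort("Scan interval must be positive.")
  (log(s2) - log(s1)) / interval
}

#' Convert PiB SUVR to centiloid
#'
#' The tracer- and pipeline-specific affine calibration
#' `CL = 100 * ((-0.1620 + 0.9467 * S) - 1.009) / 1.067`. Strictly
#' increasing, so sample quantiles commute with the conversion.
#'
#' @param s SUVR (vectorized).
#' @return Centiloid value(s).
#' @examples
#' suvr_to_centiloid(1.44)  # ~18.0
#' @export
suvr_to_centiloid <- function(s) {
  100 * ((-0.1620 + 0.9467 * s) - 1.009) / 1.067
}

#' Classify baseline amyloid status
#'
#' PiB-positive iff baseline global SUVR >= 1.48 (boundary inclusive).
#'
#' @param s Baseline global SUVR (vectorized).
#' @return Factor with levels `PiB-`, `PiB+`.
#' @export
classify_pib <- function(s) {
  if (any(s <= 0)) abort("SUVRs must be positive.")
  factor(ifelse(s >= PIB_POS_CUTOFF, "PiB+", "PiB-"), levels = c("PiB-", "PiB+"))
}

#' Annualize two-timepoint PET for a cohort table
#'
#' Tidy wrapper: takes a cohort table holding per-ROI SUVR columns at two
#' timepoints (`<roi>_suvr1`, `<roi>_suvr2`), scan dates or an interval, and
#' appends global SUVR/CL at both timepoints, baseline amyloid status, and
#' global plus per-ROI annualized log-scale changes (`delta_pib_log_yr`,
#' `<roi>_delta_log_yr`) and the centiloid-difference rate `delta_pib_cl_yr`
#' (computed as the difference of CL-converted SUVRs per year).
#'
#' @param scans Data frame; per-ROI columns as above, plus either
#'   `interval_years` or `scan1_date`/`scan2_date` (Dates).
#' @param rois ROI name stems (default the six study ROIs).
#' @param weights Optional ROI weights for the global average.
#' @return The input tibble with appended columns.
#' @export
annualize_pib <- function(scans, rois = PIB_ROIS, weights = NULL) {
  d <- as_tibble(scans)
  if (!"interval_years" %in% names(d)) {
    if (!all(c("scan1_date", "scan2_date") %in% names(d))) {
      abort("Need `interval_years` or `scan1_date`/`scan2_date`.")
    }
    d$interval_years <- as.numeric(difftime(d$scan2_date, d$scan1_date,
                                            units = "days")) / 365.25
  }
  c1 <- paste0(rois, "_suvr1"); c2 <- paste0(rois, "_suvr2")
  miss <- setdiff(c(c1, c2), names(d))
  if (length(miss) > 0) abort(paste0("Missing ROI column(s): ", paste(miss, collapse = ", ")))
  m1 <- as.matrix(d[c1]); m2 <- as.matrix(d[c2])
  w <- weights %||% rep(1, length(rois))
  d$global_suvr1 <- as.vector(m1 %*% w) / sum(w)
  d$global_suvr2 <- as.vector(m2 %*% w) / sum(w)
  d$global_cl1 <- suvr_to_centiloid(d$global_suvr1)
  d$global_cl2 <- suvr_to_centiloid(d$global_suvr2)
  d$pib_status_f <- classify_pib(d$global_suvr1)
  d$pib_status <- as.integer(d$pib_status_f == "PiB+")
  d$delta_pib_log_yr <- annualized_log_change(d$global_suvr1, d$global_suvr2,
                                              d$interval_years)
  d$delta_pib_cl_yr <- (d$global_cl2 - d$global_cl1) / d$interval_years
  for (i in seq_along(rois)) {
    d[[paste0(rois[i], "_delta_log_yr")]] <-
      annualized_log_change(unname(m1[, i]), unname(m2[, i]), d$interval_years)
  }
  d
}
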
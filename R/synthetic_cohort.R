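# Seeded synthetic cohorts with a known linear effect of slow-wave features
# on annualized amyloid accumulation. Defaults mirror the study conditions
# of an aging OSA cohort: n = 64, feature and covariate distributions from
# the descriptive tables, per-SD effects of the magnitudes reported for the
# association models.

#' Specify a synthetic cohort
#'
#' The generating model, on the annualized log-SUVR scale, is
#' `outcome = b0 + sum_k beta_k * z(feature_k) + g_age*(age - mean_age) +
#' g_apoe*apoe4 + g_pib*pib_status + e`, where `z()` standardizes by the
#' specified population mean/SD and `e ~ N(0, residual_sd^2)`. Follow-up
#' SUVR is derived from the baseline SUVR, the outcome and the scan interval,
#' so the PET annualization stage can reconstruct the outcome exactly.
#'
#' @param n Participants (default 64).
#' @param feature_means,feature_sds Named numeric for `so_pct`, `delta_pct`,
#'   `so_slope`, `delta_slope` (defaults 25.7/46.3/95.1/130.8 and
#'   6.6/5.4/28.9/34.8).
#' @param r_pct,r_slope Correlations within the (SO%, delta%) and
#'   (SO-slope, delta-slope) pairs (defaults -0.45 and 0.88; the two pairs
#'   are generated independently of each other).
#' @param beta Named per-1-SD effects on the outcome (defaults 0.0033,
#'   0.0003, 0.0069, -0.0082).
#' @param age_mean,age_sd Baseline age distribution (72.9, 7.5 years).
#' @param apoe4_prev APOE e4 carrier prevalence (0.27).
#' @param gamma Named covariate effects: `age` (per year), `apoe4`, `pib_pos`
#'   (defaults 0.0005, 0.004, 0.0104).
#' @param b0 Intercept on the outcome scale (default 0.0020, placing the
#'   mean outcome near 0.008 log-SUVR/year once covariate effects are added).
#' @param residual_sd Residual SD of the outcome (default 0.010).
#' @param suvr_meanlog,suvr_sdlog Baseline global SUVR lognormal parameters
#'   (defaults log(1.42), 0.16; amyloid positivity is the SUVR >= 1.48
#'   indicator, giving ~39% prevalence).
#' @param interval_meanlog,interval_sdlog Scan interval lognormal parameters
#'   (defaults log(2.7), 0.25 years).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 64,
                        feature_means = c(so_pct = 25.7, delta_pct = 46.3,
                                          so_slope = 95.1, delta_slope = 130.8),
                        feature_sds = c(so_pct = 6.6, delta_pct = 5.4,
                                        so_slope = 28.9, delta_slope = 34.8),
                        r_pct = -0.45, r_slope = 0.88,
                        beta = c(so_pct = 0.0033, delta_pct = 0.0003,
                                 so_slope = 0.0069, delta_slope = -0.0082),
                        age_mean = 72.9, age_sd = 7.5,
                        apoe4_prev = 0.27,
                        gamma = c(age = 0.0005, apoe4 = 0.004, pib_pos = 0.0104),
                        b0 = 0.0020, residual_sd = 0.010,
                        suvr_meanlog = log(1.42), suvr_sdlog = 0.16,
                        interval_meanlog = log(2.7), interval_sdlog = 0.25,
                        seed = 1L) {
  if (residual_sd <= 0) abort("residual_sd must be > 0.")
  n_terms <- length(beta) + length(gamma)
  if (n < n_terms + 2) abort(sprintf("n = %d too small for %d model terms.", n, n_terms))
  structure(as.list(environment()), class = "cohort_spec")
}

#' Synthesize a cohort table with known generating parameters
#'
#' @param spec A `cohort_spec`.
#' @return List with `cohort` (tibble, one row per participant) and `truth`
#'   (the generating parameters: `beta` per 1 SD, `gamma`, `b0`,
#'   `residual_sd`). Cohort columns include demographics (`age`, `apoe4`),
#'   PET quantities (`suvr_baseline`, `suvr_followup`, `interval_years`,
#'   `pib_status`), PSG summaries (`tst_min`, `n3_pct`, `effective_pap`,
#'   `psg_pet_interval`), the four slow-wave features and their ratios, and
#'   the outcome `delta_pib_log_yr` (with its centiloid counterpart
#'   `delta_pib_cl_yr`).
#' @export
synthesize_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, synthesize_cohort_impl(spec))
}

synthesize_cohort_impl <- function(spec) {
  n <- spec$n
  fm <- spec$feature_means; fsd <- spec$feature_sds
  S_pct <- diag(fsd[c("so_pct", "delta_pct")]^2)
  S_pct[1, 2] <- S_pct[2, 1] <- spec$r_pct * fsd["so_pct"] * fsd["delta_pct"]
  S_sl <- diag(fsd[c("so_slope", "delta_slope")]^2)
  S_sl[1, 2] <- S_sl[2, 1] <- spec$r_slope * fsd["so_slope"] * fsd["delta_slope"]
  pct <- MASS::mvrnorm(n, fm[c("so_pct", "delta_pct")], S_pct)
  sl <- MASS::mvrnorm(n, fm[c("so_slope", "delta_slope")], S_sl)
  feats <- cbind(pct, sl)
  colnames(feats) <- c("so_pct", "delta_pct", "so_slope", "delta_slope")
  feats <- pmax(feats, 1)                       # physical floor

  age <- rnorm(n, spec$age_mean, spec$age_sd)
  apoe4 <- stats::rbinom(n, 1, spec$apoe4_prev)
  suvr1 <- stats::rlnorm(n, spec$suvr_meanlog, spec$suvr_sdlog)
  pib_pos <- as.integer(suvr1 >= 1.48)
  interval <- stats::rlnorm(n, spec$interval_meanlog, spec$interval_sdlog)

  z <- sweep(sweep(feats, 2, fm[colnames(feats)]), 2, fsd[colnames(feats)], "/")
  lin <- spec$b0 +
    as.vector(z %*% spec$beta[colnames(feats)]) +
    spec$gamma["age"] * (age - spec$age_mean) +
    spec$gamma["apoe4"] * apoe4 +
    spec$gamma["pib_pos"] * pib_pos
  outcome <- lin + rnorm(n, 0, spec$residual_sd)
  suvr2 <- suvr1 * exp(outcome * interval)

  cohort <- tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = age, apoe4 = apoe4,
    suvr_baseline = suvr1, suvr_followup = suvr2,
    interval_years = interval, pib_status = pib_pos,
    psg_pet_interval = rnorm(n, 0.7, 1.1),
    tst_min = pmax(60, rnorm(n, 168, 45)),
    n3_pct = pmax(0, rnorm(n, 16, 13)),
    effective_pap = stats::rbinom(n, 1, 0.45),
    so_pct = feats[, "so_pct"], delta_pct = feats[, "delta_pct"],
    so_slope = feats[, "so_slope"], delta_slope = feats[, "delta_slope"],
    so_delta_pct_ratio = feats[, "so_pct"] / feats[, "delta_pct"],
    so_delta_slope_ratio = feats[, "so_slope"] / feats[, "delta_slope"],
    delta_pib_log_yr = outcome,
    delta_pib_cl_yr = (suvr_to_centiloid(suvr2) - suvr_to_centiloid(suvr1)) / interval
  )
  list(cohort = cohort,
       truth = list(beta = spec$beta, gamma = spec$gamma, b0 = spec$b0,
                    residual_sd = spec$residual_sd,
                    feature_means = fm, feature_sds = fsd))
}
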
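# Association stage: per-SD standardized linear models with classical
# inference, backward elimination on the probability of F for removal,
# collinearity checks, correlations, paired comparisons with Cohen's d,
# and predictions at feature quantiles.

#' Standardize to z-scores with sample SD
#'
#' `(x - mean) / sd` with the n-1 denominator. The centering and scale used
#' are attached as attributes `center` and `scale` for back-conversion of
#' per-SD coefficients.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Z-scored vector with attributes `center` and `scale`.
#' @export
standardize <- function(x) {
  if (length(unique(x[!is.na(x)])) < 2) abort("Cannot standardize: fewer than 2 distinct values.")
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  structure((x - m) / s, center = m, scale = s)
}

zscore <- standardize   # internal alias (fit_ols takes a `standardize` argument)

#' Fit a multiple linear regression with classical inference
#'
#' Ordinary least squares of `outcome` on `terms`, with t-based 95%
#' confidence intervals and p-values, adjusted R-squared and a variance
#' inflation factor per non-intercept term (closed form: the diagonal of the
#' inverse correlation matrix of the predictors). Terms named in
#' `standardize` are z-scored with the sample SD before fitting, so their
#' coefficients read as change in outcome per 1 SD of the predictor.
#'
#' @param data Data frame.
#' @param outcome Outcome column name (character).
#' @param terms Character vector of predictor column names.
#' @param standardize Subset of `terms` to z-score (default none).
#' @param conf_level Confidence level (default 0.95).
#' @return A `swa_ols` object; see [tidy.swa_ols()] and [glance.swa_ols()].
#' @export
fit_ols <- function(data, outcome, terms, standardize = character(), conf_level = 0.95) {
  d <- as_tibble(data)[, c(outcome, terms)]
  if (anyNA(d)) {
    n0 <- nrow(d)
    d <- d[complete.cases(d), ]
    warn(sprintf("Dropped %d row(s) with missing values.", n0 - nrow(d)))
  }
  if (nrow(d) <= length(terms) + 1) abort("Too few rows for the number of terms.")
  scaling <- list()
  for (tm in standardize) {
    z <- zscore(d[[tm]])
    scaling[[tm]] <- list(center = attr(z, "center"), scale = attr(z, "scale"))
    d[[tm]] <- as.numeric(z)
  }
  f <- stats::reformulate(terms, response = outcome)
  fit <- lm(f, data = d)
  if (anyNA(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Rank-deficient design; aliased term(s): ",
                 paste(aliased, collapse = ", ")))
  }
  X <- model.matrix(fit)[, -1, drop = FALSE]
  vif <- if (ncol(X) > 1) diag(solve(stats::cor(X))) else setNames(1, colnames(X))
  structure(list(model = fit, data = d, outcome = outcome, terms = terms,
                 scaling = scaling, vif = vif, conf_level = conf_level,
                 n = nrow(d)),
            class = "swa_ols")
}

#' @export
print.swa_ols <- function(x, ...) {
  cat(sprintf("<swa_ols> %s ~ %s  (n = %d, adj. R^2 = %.3f)\n",
              x$outcome, paste(x$terms, collapse = " + "), x$n,
              summary(x$model)$adj.r.squared))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy and glance methods for fitted association models
#'
#' `tidy()` returns one row per coefficient with the t-based confidence
#' interval and the term's variance inflation factor; `glance()` returns
#' one-row model-level summaries.
#'
#' @param x A `swa_ols` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.swa_ols <- function(x, ...) {
  s <- summary(x$model)$coefficients
  ci <- stats::confint(x$model, level = x$conf_level)
  tibble(
    term = rownames(s),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4]),
    conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2]),
    vif = unname(c(NA_real_, x$vif[rownames(s)[-1]]))
  )
}

#' @rdname tidy.swa_ols
#' @export
glance.swa_ols <- function(x, ...) {
  s <- summary(x$model)
  fstat <- s$fstatistic
  tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(fstat[1]),
    p.value = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    df = unname(fstat[2]), nobs = x$n
  )
}

#' Backward elimination by probability of F for removal
#'
#' Starting from the full model, repeatedly removes the eligible term with
#' the largest partial-F p-value while that p-value exceeds `p_remove`
#' (default 0.1). For a single-df term the partial-F p-value equals the
#' coefficient's t-test p-value. Terms in `forced_in` (typically the
#' slow-wave exposure under test) are never removed.
#'
#' @inheritParams fit_ols
#' @param forced_in Terms exempt from removal (must be a subset of `terms`).
#' @param p_remove Removal threshold (default 0.1); a term with p equal to
#'   the threshold is retained.
#' @return List with `fit` (final `swa_ols`) and `trace` (tibble of removed
#'   terms in order, with the p-value at removal).
#' @export
backward_eliminate <- function(data, outcome, terms, forced_in = character(),
                               p_remove = 0.1, standardize = character()) {
  if (!all(forced_in %in% terms)) abort("`forced_in` must be a subset of `terms`.")
  current <- terms
  trace <- tibble(step = integer(), term = character(), p.value = numeric())
  repeat {
    fit <- fit_ols(data, outcome, current, standardize = intersect(standardize, current))
    tt <- tidy(fit)
    cand <- tt[tt$term %in% setdiff(current, forced_in), ]
    if (nrow(cand) == 0 || max(cand$p.value) <= p_remove) break
    worst <- cand$term[which.max(cand$p.value)]
    trace <- bind_rows(trace, tibble(step = nrow(trace) + 1L, term = worst,
                                     p.value = max(cand$p.value)))
    current <- setdiff(current, worst)
  }
  list(fit = fit, trace = trace)
}

#' Bivariate correlation with optional log transforms
#'
#' Pearson's r (default) or Spearman's rank coefficient with a two-sided
#' p-value, optionally log-transforming either variable first (as done when
#' a skewed variable is linearized before correlation).
#'
#' @param data Data frame.
#' @param x,y Column names (character).
#' @param method `"pearson"` or `"spearman"`.
#' @param log_x,log_y Log-transform the variable first (values must be > 0).
#' @return One-row tibble: `estimate`, `p.value`, `method`, `n`.
#' @export
correlate <- function(data, x, y, method = c("pearson", "spearman"),
                      log_x = FALSE, log_y = FALSE) {
  method <- match.arg(method)
  xv <- data[[x]]; yv <- data[[y]]
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("Need at least 3 complete pairs.")
  if (log_x) xv <- log(xv)
  if (log_y) yv <- log(yv)
  if (sd(xv) == 0 || sd(yv) == 0) abort("Constant input; correlation undefined.")
  ct <- suppressWarnings(cor.test(xv, yv, method = method, exact = FALSE))
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
         method = method, n = length(xv))
}

#' Paired comparison with Cohen's d for paired samples
#'
#' Two-sided paired t-test of `a - b` with the t-based confidence interval,
#' and the paired-samples effect size `d = mean(diff) / sd(diff)`. The SD of
#' the differences is the sample SD adjusted by the correlation between the
#' two measures, since `sd(diff)^2 = s_a^2 + s_b^2 - 2 r s_a s_b`.
#'
#' @param a,b Equal-length paired numeric vectors (n >= 3).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `n`, `mean_diff`, `conf.low`, `conf.high`,
#'   `p.value`, `cohens_d`, `sd_diff`.
#' @export
paired_compare <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) abort("Paired vectors must have equal length.")
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) abort("Need at least 3 complete pairs.")
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      # identical vectors: no shift, null effect; no t-based inference possible
      return(tibble(n = length(a), mean_diff = 0, conf.low = 0, conf.high = 0,
                    p.value = NA_real_, cohens_d = 0, sd_diff = 0))
    }
    abort("Zero variance of paired differences; d undefined.")
  }
  tt <- t.test(a, b, paired = TRUE, conf.level = conf_level)
  tibble(
    n = length(a),
    mean_diff = unname(tt$estimate),
    conf.low = tt$conf.int[1], conf.high = tt$conf.int[2],
    p.value = tt$p.value,
    cohens_d = mean(d) / sd(d),
    sd_diff = sd(d)
  )
}

#' Predicted outcomes at feature quantiles
#'
#' Evaluates a fitted model's linear predictor at sample quantiles of one
#' feature, holding every other term at a stated covariate profile (e.g.
#' means for continuous covariates and reference categories for indicators;
#' for paired slope features, the companion feature is typically held in its
#' own 50-75th-percentile band).
#'
#' @param fit A `swa_ols`.
#' @param feature One of the fit's terms; quantiles are taken from its
#'   distribution in the fitting data (on the natural scale).
#' @param quantiles Numeric probabilities in (0, 1).
#' @param profile Named list/vector giving the value of every other term, on
#'   the natural scale.
#' @return Tibble: `quantile`, `feature_value` (natural scale), `predicted`.
#' @export
predict_at_quantiles <- function(fit, feature, quantiles, profile) {
  stopifnot(inherits(fit, "swa_ols"))
  if (!feature %in% fit$terms) abort("`feature` is not a term of the fit.")
  if (any(quantiles <= 0 | quantiles >= 1)) abort("Quantiles must lie in (0, 1).")
  others <- setdiff(fit$terms, feature)
  miss <- setdiff(others, names(profile))
  if (length(miss) > 0) {
    abort(paste0("Profile must set every other term; missing: ",
                 paste(miss, collapse = ", ")))
  }
  # recover the feature's natural-scale sample values from the fitting data
  fv <- fit$data[[feature]]
  sc <- fit$scaling[[feature]]
  if (!is.null(sc)) fv <- fv * sc$scale + sc$center
  qv <- quantile(fv, quantiles, names = FALSE, type = 7)
  newdata <- as_tibble(c(setNames(list(qv), feature),
                         lapply(profile[others], rep, length(qv))))
  # apply the fit's standardization to the new data
  for (tm in names(fit$scaling)) {
    s <- fit$scaling[[tm]]
    newdata[[tm]] <- (newdata[[tm]] - s$center) / s$scale
  }
  tibble(quantile = quantiles, feature_value = qv,
         predicted = unname(predict(fit$model, newdata = newdata)))
}

#' Benjamini-Hochberg adjustment for a results table
#'
#' Optional multiplicity adjustment (off by default throughout the package,
#' matching an exploratory analysis posture): appends `p.adjusted` to any
#' tibble with a `p.value` column.
#'
#' @param tbl Tibble with a `p.value` column.
#' @param method Passed to [stats::p.adjust()] (default `"BH"`).
#' @return `tbl` with `p.adjusted` appended.
#' @export
adjust_p <- function(tbl, method = "BH") {
  mutate(tbl, p.adjusted = stats::p.adjust(.data$p.value, method = method))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
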
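test_that("standardize uses the sample SD and reports its scale", {
  z <- standardize(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(attr(z, "scale"), 1)
  set.seed(2)
  z2 <- standardize(rnorm(50, 10, 4))
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sd(z2), 1, tolerance = 1e-12)
  expect_error(standardize(rep(3, 5)), "distinct")
})

test_that("per-SD coefficients equal unstandardized coefficients times SD", {
  set.seed(7)
  d <- tibble::tibble(x = rnorm(80, 50, 9), w = rnorm(80))
  d$y <- 0.3 * d$x + 2 * d$w + rnorm(80)
  raw <- tidy(fit_ols(d, "y", c("x", "w")))
  std <- tidy(fit_ols(d, "y", c("x", "w"), standardize = "x"))
  expect_equal(std$estimate[std$term == "x"],
               raw$estimate[raw$term == "x"] * sd(d$x), tolerance = 1e-12)
})

test_that("fit_ols matches the brute-force normal-equations oracle", {
  set.seed(31)
  d <- tibble::tibble(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  d$y <- 1.5 * d$a - 0.7 * d$b + rnorm(60, 0, 0.5)
  fit <- fit_ols(d, "y", c("a", "b", "c"))
  tt <- tidy(fit)
  o <- oracle_ols(cbind(1, d$a, d$b, d$c), d$y)
  expect_equal(tt$estimate, o$beta, tolerance = 1e-10)
  expect_equal(tt$std.error, unname(o$se), tolerance = 1e-10)
  expect_equal(tt$conf.low, o$beta - qt(0.975, o$df) * o$se,
               tolerance = 1e-10, ignore_attr = TRUE)

  # noise-free single predictor: exact coefficient, R^2 = 1
  # (lm warns about the perfect fit; that is the point of the fixture)
  d2 <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  fit2 <- fit_ols(d2, "y", "x")
  suppressWarnings({
    expect_equal(tidy(fit2)$estimate[2], 2)
    expect_equal(glance(fit2)$r.squared, 1)
    expect_gte(glance(fit2)$r.squared, glance(fit2)$adj.r.squared)
  })
})

test_that("VIF follows the closed form and flags collinearity", {
  # construct two predictors with exact correlation 0.88
  set.seed(13)
  n <- 400
  u <- rnorm(n); v <- rnorm(n)
  u <- as.numeric(scale(u)); v <- as.numeric(scale(residuals(lm(v ~ u))))
  r <- 0.88
  x2 <- r * u + sqrt(1 - r^2) * v
  d <- tibble::tibble(x1 = u, x2 = x2, y = rnorm(n))
  expect_equal(cor(d$x1, d$x2), 0.88, tolerance = 1e-12)
  fit <- fit_ols(d, "y", c("x1", "x2"))
  expect_equal(unname(fit$vif), rep(1 / (1 - 0.88^2), 2), tolerance = 1e-10)
  expect_lte(max(fit$vif), 5)

  # independent cross-check against car's implementation
  expect_equal(unname(fit$vif), unname(car::vif(fit$model)), tolerance = 1e-10)

  # aliased designs error with the offending term named
  d$x3 <- d$x1
  expect_error(fit_ols(d, "y", c("x1", "x3")), "aliased.*x3")
})

test_that("backward elimination honors the removal threshold and forcing", {
  set.seed(41)
  n <- 200
  d <- tibble::tibble(strong = rnorm(n), noise = rnorm(n))
  d$y <- 1 * d$strong + rnorm(n, 0, 0.5)
  be <- backward_eliminate(d, "y", c("strong", "noise"))
  expect_true("strong" %in% be$fit$terms)
  expect_false("noise" %in% be$fit$terms)
  expect_equal(be$trace$term, "noise")

  # all terms forced: identical to the plain fit
  be2 <- backward_eliminate(d, "y", c("strong", "noise"),
                            forced_in = c("strong", "noise"))
  expect_equal(tidy(be2$fit), tidy(fit_ols(d, "y", c("strong", "noise"))))
  expect_equal(nrow(be2$trace), 0)

  # p_remove = 1 keeps the full model; p_remove = 0 keeps only forced terms
  be3 <- backward_eliminate(d, "y", c("strong", "noise"), p_remove = 1)
  expect_setequal(be3$fit$terms, c("strong", "noise"))
  be4 <- backward_eliminate(d, "y", c("strong", "noise"),
                            forced_in = "noise", p_remove = 0)
  expect_equal(be4$fit$terms, "noise")

  # a term sitting exactly at the threshold is retained (removal on exceedance)
  # construct: single candidate with p ~ 0.09
  set.seed(4)
  repeat {
    d2 <- tibble::tibble(x = rnorm(100)); d2$y <- 0.17 * d2$x + rnorm(100)
    p <- tidy(fit_ols(d2, "y", "x"))$p.value[2]
    if (p > 0.085 && p < 0.1) break
  }
  be5 <- backward_eliminate(d2, "y", "x")
  expect_equal(be5$fit$terms, "x")
})

test_that("elimination retains strong terms and drops pure noise at its nominal rate", {
  res <- purrr::map(1:60, function(i) {
    set.seed(300 + i)
    n <- 200
    d <- tibble::tibble(strong = rnorm(n), noise = rnorm(n))
    d$y <- 0.8 * d$strong + rnorm(n)
    be <- backward_eliminate(d, "y", c("strong", "noise"))
    c(strong = "strong" %in% be$fit$terms, noise = "noise" %in% be$fit$terms)
  })
  strong_kept <- mean(purrr::map_lgl(res, "strong"))
  noise_kept <- mean(purrr::map_lgl(res, "noise"))
  expect_equal(strong_kept, 1)
  # a null covariate survives the 0.1 removal threshold ~10% of the time
  expect_lt(noise_kept, 0.25)
})

test_that("correlations match their rank/linear definitions", {
  d <- tibble::tibble(x = 1:20, y = 1:20)
  expect_equal(correlate(d, "x", "y")$estimate, 1)

  d2 <- tibble::tibble(x = seq(0, 3, length.out = 30))
  d2$y <- exp(d2$x)
  expect_equal(correlate(d2, "x", "y", method = "spearman")$estimate, 1)
  expect_lt(correlate(d2, "x", "y", method = "pearson")$estimate, 1)
  # log transform linearizes the exponential relation
  expect_equal(correlate(d2, "x", "y", log_y = TRUE)$estimate, 1)

  set.seed(3)
  d3 <- tibble::tibble(x = rnorm(25), y = rnorm(25))
  expect_equal(correlate(d3, "x", "y", method = "spearman")$estimate,
               cor(rank(d3$x), rank(d3$y)))
  expect_error(correlate(tibble::tibble(x = rep(1, 5), y = 1:5), "x", "y"),
               "Constant")
})

test_that("paired comparison returns the paired-sample effect size", {
  set.seed(19)
  a <- rnorm(30, 10, 3)
  b <- a - rnorm(30, 1, 2)
  pc <- paired_compare(a, b)
  d <- a - b
  expect_equal(pc$mean_diff, mean(d))
  expect_equal(pc$cohens_d, mean(d) / sd(d))
  # CI symmetric about the mean difference; consistent with sd(diff) identity
  expect_equal((pc$conf.low + pc$conf.high) / 2, pc$mean_diff)
  expect_equal(pc$sd_diff^2, var(a) + var(b) - 2 * cor(a, b) * sd(a) * sd(b),
               tolerance = 1e-12)
  # identical vectors: null effect with d = 0; constant non-zero shift: undefined
  same <- paired_compare(a, a)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$cohens_d, 0)
  expect_error(paired_compare(a, a - 3), "Zero variance")
  expect_error(paired_compare(a, b[1:10]), "equal length")
})

test_that("quantile predictions match a direct linear-predictor product", {
  set.seed(23)
  n <- 120
  d <- tibble::tibble(f = rnorm(n, 100, 25), g = rnorm(n, 50, 10),
                      age = rnorm(n, 73, 7))
  d$y <- 0.01 * d$f - 0.005 * d$g + 0.002 * d$age + rnorm(n, 0, 0.5)
  fit <- fit_ols(d, "y", c("f", "g", "age"), standardize = c("f", "g"))
  prof <- list(g = median(d$g), age = 73)
  pred <- predict_at_quantiles(fit, "f", c(0.375, 0.875), prof)
  # brute force: beta %*% x at the same natural-scale points
  b <- coef(fit$model)
  zf <- (pred$feature_value - attr(standardize(d$f), "center")) /
    attr(standardize(d$f), "scale")
  zg <- (prof$g - attr(standardize(d$g), "center")) / attr(standardize(d$g), "scale")
  manual <- b[1] + b["f"] * zf + b["g"] * zg + b["age"] * 73
  expect_equal(pred$predicted, unname(manual), tolerance = 1e-12)
  # positive coefficient: higher quartile, higher prediction
  expect_gt(pred$predicted[2], pred$predicted[1])

  expect_error(predict_at_quantiles(fit, "f", c(0, 0.5), prof), "in \\(0, 1\\)")
  expect_error(predict_at_quantiles(fit, "f", 0.5, list(g = 1)), "missing: age")
  expect_error(predict_at_quantiles(fit, "nope", 0.5, prof), "not a term")
})

test_that("prediction at the data means reproduces the outcome mean", {
  set.seed(29)
  d <- tibble::tibble(x = rnorm(50), w = rnorm(50))
  d$y <- d$x - d$w + rnorm(50)
  fit <- fit_ols(d, "y", c("x", "w"))
  at_means <- predict(fit$model, newdata = tibble::tibble(x = mean(d$x), w = mean(d$w)))
  expect_equal(unname(at_means), mean(d$y))
})

test_that("BH adjustment is available but untouched by default outputs", {
  tt <- tibble::tibble(p.value = c(0.01, 0.02, 0.04))
  out <- adjust_p(tt)
  expect_equal(out$p.adjusted, stats::p.adjust(tt$p.value, "BH"))
  fit <- fit_ols(tibble::tibble(x = rnorm(20), y = rnorm(20)), "y", "x")
  expect_false("p.adjusted" %in% names(tidy(fit)))
})
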
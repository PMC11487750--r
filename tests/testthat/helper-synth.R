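# Shared fixtures, generated in code.

FS <- 500

sine <- function(freq, amp = 1, dur = 30, fs = FS, phase = 0) {
  t <- (seq_len(dur * fs) - 1) / fs
  amp * sin(2 * pi * freq * t + phase)
}

# Small 4-channel recording whose Fz carries `x`, references silent.
tiny_recording <- function(x, fs = FS) {
  n <- length(x)
  psg_recording(list(Fz = x, Cz = numeric(n), A1 = numeric(n), A2 = numeric(n)),
                fs = fs)
}

# Independent loop-based half-wave oracle: enumerates zero-crossing pairs
# one by one and applies the period-window / trough / threshold definitions
# directly, without any of the vectorized bookkeeping of the implementation.
oracle_halfwaves <- function(x, fs, amp_threshold = -5) {
  desc <- c(); asc <- c()
  for (i in seq_len(length(x) - 1)) {
    if (x[i] > 0 && x[i + 1] <= 0) desc <- c(desc, i)
    if (x[i] <= 0 && x[i + 1] > 0) asc <- c(asc, i)
  }
  tcross <- function(i) (i - 1 + x[i] / (x[i] - x[i + 1])) / fs
  out <- list()
  if (length(desc) < 2) {
    return(data.frame(band = character(), t_zero_cross = numeric(),
                      t_trough = numeric(), trough_amp = numeric()))
  }
  for (k in seq_len(length(desc) - 1)) {
    t0 <- tcross(desc[k]); t1 <- tcross(desc[k + 1])
    sep <- t1 - t0
    band <- if (sep >= 1.1 && sep <= 2) "SO"
            else if (sep >= 0.25 && sep <= 1.0) "delta" else NA
    if (is.na(band)) next
    lo <- desc[k] + 1; hi <- desc[k + 1]
    best <- lo
    for (j in lo:hi) if (x[j] < x[best]) best <- j
    if (x[best] > amp_threshold) next
    out[[length(out) + 1]] <- data.frame(
      band = band, t_zero_cross = t0, t_trough = (best - 1) / fs,
      trough_amp = x[best])
  }
  if (length(out) == 0) {
    return(data.frame(band = character(), t_zero_cross = numeric(),
                      t_trough = numeric(), trough_amp = numeric()))
  }
  do.call(rbind, out)
}

# Brute-force OLS via the normal equations, with classical SEs.
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(sigma2 * solve(XtX)))
  list(beta = as.vector(beta), se = se, df = df)
}
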
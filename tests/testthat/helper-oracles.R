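# Independent reference implementations used as oracles. These deliberately
# use the most direct (slow) formulations so they share no code path with the
# package.

# Literal triple-loop Higuchi curve length.
ref_curve_length <- function(x, m, k) {
  n <- length(x)
  imax <- floor((n - m) / k)
  s <- 0
  for (i in seq_len(imax)) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
  s * (n - 1) / (imax * k) / k
}

# Reference HFD: explicit loops + lm().
ref_hfd <- function(x, k_max = 8) {
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    acc <- 0
    for (m in seq_len(k)) acc <- acc + ref_curve_length(x, m, k)
    lk[k] <- acc / k
  }
  unname(stats::coef(stats::lm(log(lk) ~ log(1 / seq_len(k_max))))[2])
}

# Independent fGn generator: Cholesky factor of the exact autocovariance
# matrix (O(n^3); keep n modest). Shares nothing with circulant embedding.
ref_fgn_chol <- function(n, hurst) {
  g <- function(k) 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                            abs(k - 1)^(2 * hurst))
  sigma <- outer(seq_len(n), seq_len(n), function(i, j) g(i - j))
  as.numeric(t(chol(sigma)) %*% rnorm(n))
}

# Closed-form 2x2 binary metrics for the confusion-matrix oracle.
ref_binary_metrics <- function(tp, fn, fp, tn) {
  div0 <- function(a, b) if (b == 0) 0 else a / b
  prec <- div0(tp, tp + fp)
  rec <- div0(tp, tp + fn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    tp_rate = rec,
    fp_rate = div0(fp, fp + tn),
    precision = prec,
    recall = rec,
    f = div0(2 * prec * rec, prec + rec),
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den
  )
}

# Hand-formula one-way ANOVA (sums of squares written out).
ref_anova_f <- function(v, g) {
  g <- factor(g)
  grand <- mean(v)
  ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(v) - nlevels(g)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Small helper: a recording with the given channel rows.
make_rec <- function(..., rate_hz = 250) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  eeg_recording(m, rate_hz = rate_hz,
                montage = montage_1020()$names[seq_len(nrow(m))])
}

# Jittered XOR data, the canonical nonlinearly-separable configuration.
make_xor <- function(n = 40, jitter = 0.05, seed = 1) {
  set.seed(seed)
  x <- data.frame(a = rep(c(0, 1, 0, 1), n / 4) + rnorm(n, 0, jitter),
                  b = rep(c(0, 0, 1, 1), n / 4) + rnorm(n, 0, jitter))
  list(x = x, y = ifelse(round(x$a) != round(x$b), "on", "off"))
}
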
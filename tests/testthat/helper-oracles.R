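# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: plain loops and direct formula transcriptions.

# per-sample brute-force ENMO in mg (sample-level truncation)
oracle_enmo <- function(samples) {
  total <- 0
  for (i in seq_len(nrow(samples))) {
    r <- sqrt(samples[i, 1]^2 + samples[i, 2]^2 + samples[i, 3]^2)
    total <- total + max(r - 1, 0)
  }
  1000 * total / nrow(samples)
}

# brute-force MAD in mg
oracle_mad <- function(samples) {
  r <- numeric(nrow(samples))
  for (i in seq_len(nrow(samples)))
    r[i] <- sqrt(sum(samples[i, ]^2))
  1000 * sum(abs(r - mean(r))) / length(r)
}

# exhaustive window enumeration for bout minutes: marks every epoch covered
# by some window [i, j] with length >= w epochs, first/last above threshold,
# and >= tol fraction above
oracle_bout_minutes <- function(above, w, tol, epoch_min) {
  n <- length(above)
  covered <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!above[i]) next
    for (j in i:n) {
      if (!above[j] || j - i + 1 < w) next
      if (sum(above[i:j]) >= tol * (j - i + 1) - 1e-9)
        covered[i:j] <- TRUE
    }
  }
  sum(covered) * epoch_min
}

# closed-form agreement ICC for the mean of k days drawn from a pool of p
# days, compared against the full p-day mean (subset and reference share
# days): Cov = sb^2 + sw^2/p, Var(sub) = sb^2 + sw^2/k
oracle_overlap_icc <- function(k, p, sb, sw) {
  (sb^2 + sw^2 / p) / (sb^2 + sw^2 * (1 / (2 * k) + 1 / (2 * p)))
}

# ICC(A,1) from an explicit two-way ANOVA via aov(), n subjects x 2 raters
oracle_icc_aov <- function(x, y) {
  d <- data.frame(score = c(x, y),
                  subject = factor(rep(seq_along(x), 2)),
                  rater = factor(rep(1:2, each = length(x))))
  ms <- anova(aov(score ~ subject + rater, data = d))
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  n <- length(x)
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}
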
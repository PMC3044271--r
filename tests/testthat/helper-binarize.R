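# Exhaustive-scan oracle for the maximum-entropy threshold: a direct,
# loop-based transcription of the criterion, independent of the package's
# vectorized implementation.
kapur_oracle <- function(values, bins = 256L) {
  lo <- min(values); hi <- max(values)
  x <- (values - lo) / (hi - lo)
  b <- pmin(pmax(ceiling(x * bins), 1L), bins)
  p <- tabulate(b, nbins = bins) / length(values)
  best <- -Inf
  best_T <- NA_integer_
  for (T in seq_len(bins - 1L)) {
    pb <- p[1:T]
    pf <- p[(T + 1L):bins]
    Pb <- sum(pb); Pf <- sum(pf)
    if (Pb == 0 || Pf == 0) next
    hb <- -sum(ifelse(pb > 0, pb / Pb * log(pb / Pb), 0))
    hf <- -sum(ifelse(pf > 0, pf / Pf * log(pf / Pf), 0))
    if (hb + hf > best) {
      best <- hb + hf
      best_T <- T
    }
  }
  lo + (hi - lo) * best_T / bins
}

# balanced synthetic densitometry lane with known bits
balanced_lane <- function(seed, n_per_class = 24L, mu_off = 100,
                          mu_on = 200, sigma = 20) {
  set.seed(seed)
  bits <- sample(rep(c(0L, 1L), each = n_per_class))
  value <- ifelse(bits == 1L, mu_on, mu_off) +
    stats::rnorm(length(bits), 0, sigma)
  list(profile = data.frame(node = "X", t = seq_along(bits) * 3L,
                            value = pmax(value, 0)),
       bits = bits)
}
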
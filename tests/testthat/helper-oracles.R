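# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Textbook Pearson correlation from raw sums.
pearson_bruteforce <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

# From-scratch nMxa recomputation on a clean (unmasked) recording:
# loop-based block means, loop-based window placement, sum-formula
# Pearson, arithmetic mean over windows. No dplyr, no cor(), no package
# functions.
nmxa_oracle <- function(rec, channel, block_len_s = 10, window_s = 300,
                        step_s = 10) {
  fs <- attr(rec, "fs")
  len <- round(block_len_s * fs)
  n_blocks <- floor(nrow(rec) / len)
  ab <- numeric(n_blocks); fb <- numeric(n_blocks)
  for (i in seq_len(n_blocks)) {
    idx <- ((i - 1) * len + 1):(i * len)
    ab[i] <- sum(rec$abp[idx]) / len
    fb[i] <- sum(rec[[channel]][idx]) / len
  }
  per_win <- block_len_s
  wlen <- window_s / per_win
  wstep <- step_s / per_win
  rs <- c()
  s <- 1
  while (s + wlen - 1 <= n_blocks) {
    idx <- s:(s + wlen - 1)
    rs <- c(rs, pearson_bruteforce(ab[idx], fb[idx]))
    s <- s + wstep
  }
  mean(rs)
}

# THRR straight from its definition: mean of post-release systolic peaks
# 2..4 over the mean of the last `baseline_n` baseline systolic values.
thrr_oracle <- function(baseline, post_peaks, baseline_n = 5) {
  b <- baseline[(length(baseline) - baseline_n + 1):length(baseline)]
  (post_peaks[2] + post_peaks[3] + post_peaks[4]) / 3 / mean(b)
}

# Small fast simulation config for tests that do not need 125 Hz.
quick_config <- function(seed, duration_s = 1200, fs = 25, ...) {
  sim_config(duration_s = duration_s, fs = fs, seed = seed, ...)
}
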
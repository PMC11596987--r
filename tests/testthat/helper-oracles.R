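# Brute-force reference implementations used as independent oracles.

# BH step-up by the textbook definition: find the largest k with
# p_(k) <= k q / m, reject all smaller-or-equal p-values.
bh_bruteforce <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  sig <- logical(m)
  if (length(k)) sig[ord[seq_len(max(k))]] <- TRUE
  sig
}

# maximal runs of TRUE of length >= k, scanned element by element
runs_bruteforce <- function(ok, k) {
  runs <- list()
  i <- 1
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1]) j <- j + 1
      if (j - i + 1 >= k) runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# union of half-open intervals by pairwise sweeping
union_bruteforce <- function(start, end) {
  ord <- order(start)
  start <- start[ord]; end <- end[ord]
  out <- list()
  cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] < ce) {
      ce <- max(ce, end[i])
    } else {
      out[[length(out) + 1]] <- c(cs, ce)
      cs <- start[i]; ce <- end[i]
    }
  }
  out[[length(out) + 1]] <- c(cs, ce)
  do.call(rbind, out)
}

# per-trial hit scoring with >= 50% temporal overlap
overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

# small deterministic recording fixture
sine_recording <- function(freq = 10, duration = 2, rate = 250,
                           amplitude = 1, n_channels = 1) {
  t <- (0:(duration * rate - 1)) / rate
  data <- matrix(rep(amplitude * sin(2 * pi * freq * t), n_channels),
                 nrow = n_channels, byrow = TRUE)
  recording(data, rate)
}

# hand-made cycle table for run-detection tests (properties preset)
fake_cycles <- function(qualify, period = 0.1, amplitude = 1) {
  n <- length(qualify)
  start <- (0:(n - 1)) * period
  data.frame(start = start, end = start + period, peak = start,
             trough = start + period / 2, period = period,
             amplitude = amplitude,
             peak_idx = NA, peak_idx2 = NA, trough_idx = NA,
             monotonicity = ifelse(qualify, 1, 0),
             period_consistency = 1, amplitude_consistency = 1)
}
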
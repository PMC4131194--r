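# Independent brute-force recomputation of the gain statistics, written
# loop-by-loop from the definitions. Used to cross-check the vectorized
# implementations; deliberately shares no code with the package internals.

oracle_mask <- function(counts) {
  n <- length(counts)
  # primary run: first nonzero, extend while strictly increasing
  start <- 0
  for (i in seq_len(n)) if (counts[i] > 0) { start <- i; break }
  inc <- rep(FALSE, n)
  if (start > 0) {
    end <- start
    while (end < n && counts[end + 1] > counts[end]) end <- end + 1
    if (end - start + 1 >= 3) {
      inc[start:end] <- TRUE
      return(inc)
    }
    # fallback: longest strictly increasing run of positive counts
    best <- c(0, -1)
    i <- 1
    while (i <= n) {
      if (counts[i] > 0) {
        j <- i
        while (j < n && counts[j + 1] > counts[j]) j <- j + 1
        if (j - i > best[2] - best[1]) best <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    if (best[1] > 0 && best[2] - best[1] + 1 >= 3) inc[best[1]:best[2]] <- TRUE
  }
  inc
}

oracle_io_stats <- function(frequency, amplitudes, counts) {
  inc <- oracle_mask(counts)
  k <- which(inc)
  if (length(k) < 3) return(list(asl_f = NA_real_, var_f = NA_real_))
  d <- numeric(length(k) - 1)
  for (j in seq_along(d)) d[j] <- counts[k[j + 1]] - counts[k[j]]
  m <- sum(d) / length(d)
  ss <- 0
  for (x in d) ss <- ss + (x - m)^2
  list(asl_f = m / sqrt(frequency),
       var_f = ss / (length(d) - 1) / frequency)
}

oracle_offset <- function(frequency, amplitudes, counts) {
  for (i in seq_along(counts)) {
    if (counts[i] > frequency / 2) return(amplitudes[i] / frequency^0.25)
  }
  NA_real_
}

# random fixture curve on the 50 pA grid: leading zeros, noisy quasi-monotone
# rise, occasional plateau/dip
random_io_curve_counts <- function(n_amp = 9) {
  n_lead <- sample(0:3, 1)
  c0 <- sample(1:6, 1)
  steps <- sample(0:6, n_amp - n_lead - 1, replace = TRUE)
  counts <- c(rep(0, n_lead), c0 + cumsum(c(0, steps)))
  if (runif(1) < 0.3) counts[length(counts)] <- max(counts[length(counts)] - sample(1:5, 1), 0)
  counts
}
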
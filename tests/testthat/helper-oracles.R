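# Independent oracles, deliberately written as direct definitions (double
# loops, numerical integration) rather than reusing the package's vectorized
# paths.

# correlogram by brute force: for every spike pair test each bin's half-open
# edges directly
oracle_correlogram_pair <- function(ta, tb, bin, max_lag, auto = FALSE) {
  K <- ceiling(round(max_lag / bin - 0.5, 9))
  centers <- seq(-K, K) * bin
  counts <- numeric(length(centers))
  for (i in seq_along(ta)) {
    for (j in seq_along(tb)) {
      if (auto && i == j) next
      d <- tb[j] - ta[i]
      if (abs(d) > max_lag) next
      for (k in seq_along(centers)) {
        lo <- centers[k] - bin / 2
        hi <- centers[k] + bin / 2
        if (d >= lo && d < hi) {
          counts[k] <- counts[k] + 1
          break
        }
      }
    }
  }
  list(centers = centers, counts = counts)
}

# leave-one-out bandwidth cost by numerical integration of the definition:
# integral(lambda^2) - 2 * sum_i lambda^(-i)(t_i), lambda = sum_j k_w(. - t_j)
oracle_bandwidth_cost <- function(times, w, grid_n = 20000) {
  lo <- min(times) - 8 * w
  hi <- max(times) + 8 * w
  grid <- seq(lo, hi, length.out = grid_n)
  lam <- sapply(grid, function(t) sum(dnorm(t - times, sd = w)))
  dt <- grid[2] - grid[1]
  int_lam2 <- sum((lam[-1]^2 + lam[-grid_n]^2) / 2) * dt
  loo <- sum(sapply(seq_along(times), function(i)
    sum(dnorm(times[i] - times[-i], sd = w))))
  int_lam2 - 2 * loo
}
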
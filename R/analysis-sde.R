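# Kernel spike density estimation with data-driven bandwidth selection.
#
# The rate estimate is a Gaussian kernel sum over the pooled spikes,
#   lambda_hat(t) = (1/n_trials) * sum_i k_w(t - t_i),
# with k_w(t) = exp(-t^2 / 2 w^2) / (sqrt(2 pi) w). The bandwidth w is picked
# by minimizing the leave-one-out cost in its closed form
#   C_hat(w) = sum_{i,j} k_{sqrt(2) w}(t_i - t_j) - 2 sum_{i != j} k_w(t_i - t_j),
# which equals  integral(lambda_hat^2 dt) - 2 sum_i lambda_hat^{(-i)}(t_i)
# up to terms independent of w (the convolution of two Gaussian kernels of
# width w is a Gaussian kernel of width sqrt(2) w).

#' Bandwidth selection cost for a Gaussian kernel rate estimate
#'
#' Evaluates the closed-form leave-one-out cost at one kernel width.
#'
#' @param spike_times numeric vector of pooled spike times in seconds (or a
#'   time `qty`).
#' @param w kernel width in seconds (scalar).
#' @return The cost value (scalar).
#' @export
bandwidth_cost <- function(spike_times, w) {
  tt <- if (is_qty(spike_times)) .secs(spike_times) else spike_times
  n <- length(tt)
  d <- as.vector(stats::dist(tt)) # unique |t_i - t_j|, i < j
  # sum_{i,j} over all ordered pairs = n * k(0) + 2 * sum over unordered pairs
  s2 <- n * stats::dnorm(0, sd = sqrt(2) * w) +
    2 * sum(stats::dnorm(d, sd = sqrt(2) * w))
  s1 <- 2 * sum(stats::dnorm(d, sd = w))
  s2 - 2 * s1
}

#' Optimize the kernel bandwidth for spike density estimation
#'
#' Evaluates the leave-one-out cost over a grid of candidate widths and
#' returns the minimizer (smallest width on ties). The default grid is 50
#' log-spaced widths between 1/100 and 1/2 of the spike time span.
#'
#' @param spike_times pooled spike times (time `qty` or seconds), `n >= 2`.
#' @param candidates candidate widths in seconds (or time `qty` vector),
#'   all positive.
#' @return List: `w_star` (a time `qty`), `cost_curve` (named numeric,
#'   names = candidate widths in seconds).
#' @export
optimize_bandwidth <- function(spike_times, candidates = NULL) {
  tt <- if (is_qty(spike_times)) .secs(spike_times) else spike_times
  if (length(tt) < 2L)
    stop("optimize_bandwidth: need at least 2 spikes; use a fixed bandwidth instead",
         call. = FALSE)
  if (is.null(candidates)) {
    span <- diff(range(tt))
    if (span <= 0)
      stop("optimize_bandwidth: all spikes coincide; use a fixed bandwidth instead",
           call. = FALSE)
    candidates <- exp(seq(log(span / 100), log(span / 2), length.out = 50))
  }
  ww <- if (is_qty(candidates)) .secs(candidates) else candidates
  if (any(ww <= 0)) stop("optimize_bandwidth: candidate widths must be positive",
                         call. = FALSE)
  ww <- sort(ww)
  d <- as.vector(stats::dist(tt))
  n <- length(tt)
  cost <- vapply(ww, function(w) {
    s2 <- n * stats::dnorm(0, sd = sqrt(2) * w) +
      2 * sum(stats::dnorm(d, sd = sqrt(2) * w))
    s2 - 4 * sum(stats::dnorm(d, sd = w))
  }, numeric(1))
  names(cost) <- format(ww, digits = 10, trim = TRUE, scientific = FALSE)
  list(w_star = qty(ww[which.min(cost)], "s"), cost_curve = cost)
}

#' Kernel spike density estimate
#'
#' Gaussian-kernel estimate of the firing rate from the pooled spikes of a
#' set of trains (trials), normalized per trial so the estimate is a rate in
#' Hz whose time integral approximates spikes-per-trial. With
#' `bandwidth = "optimal"` the width is chosen by [optimize_bandwidth()] on
#' the pooled spikes; units are optimized independently of one another when
#' the caller runs this per unit.
#'
#' @param trains list of spike trains (one unit's trials), or a single train.
#' @param bandwidth a time `qty`, or `"optimal"`.
#' @param grid_step evaluation grid step (time `qty`, > 0).
#' @param pad grid padding beyond the trial window, in multiples of the
#'   bandwidth (captures kernel mass near the edges).
#' @return An `sde_result`: `time_grid` (`qty` s), `rate` (`qty` Hz),
#'   `bandwidth` (`qty` s), `cost_curve` (or `NULL`), `optimized`.
#' @export
spike_density <- function(trains, bandwidth = "optimal", grid_step = qty(1, "ms"),
                          pad = 3) {
  trains <- .as_train_list(trains)
  gs <- .secs(grid_step)
  if (gs <= 0) stop("spike_density: grid_step must be positive", call. = FALSE)
  n_trials <- max(1L, length(trains))
  pooled <- sort(unlist(lapply(trains, function(tr) .secs(tr$times))))
  if (!length(pooled)) {
    warning("spike_density: no spikes; returning a zero-rate estimate", call. = FALSE)
    w0 <- if (length(trains)) min(vapply(trains, function(tr) .secs(tr$t_start), numeric(1))) else 0
    w1 <- if (length(trains)) max(vapply(trains, function(tr) .secs(tr$t_stop), numeric(1))) else 1
    grid <- seq(w0, w1, by = gs)
    return(structure(list(time_grid = qty(grid, "s"),
                          rate = qty(numeric(length(grid)), "Hz"),
                          bandwidth = NULL, cost_curve = NULL, optimized = FALSE),
                     class = "sde_result"))
  }
  cost_curve <- NULL
  optimized <- identical(bandwidth, "optimal")
  if (optimized) {
    opt <- optimize_bandwidth(pooled)
    w <- .secs(opt$w_star)
    cost_curve <- opt$cost_curve
  } else {
    w <- .secs(bandwidth)
    if (w <= 0) stop("spike_density: bandwidth must be positive", call. = FALSE)
  }
  w0 <- min(vapply(trains, function(tr) .secs(tr$t_start), numeric(1)), pooled[1]) - pad * w
  w1 <- max(vapply(trains, function(tr) .secs(tr$t_stop), numeric(1)),
            pooled[length(pooled)]) + pad * w
  grid <- seq(w0, w1, by = gs)
  # evaluate the kernel sum on the grid; spikes are sorted, so restrict each
  # grid point to spikes within 6w using a running window
  rate <- numeric(length(grid))
  lo <- 1L; hi <- 0L; n <- length(pooled)
  for (gi in seq_along(grid)) {
    t <- grid[gi]
    while (lo <= n && pooled[lo] < t - 6 * w) lo <- lo + 1L
    while (hi < n && pooled[hi + 1L] <= t + 6 * w) hi <- hi + 1L
    if (lo <= hi)
      rate[gi] <- sum(stats::dnorm(t - pooled[lo:hi], sd = w))
  }
  structure(list(time_grid = qty(grid, "s"), rate = qty(rate / n_trials, "Hz"),
                 bandwidth = qty(w, "s"), cost_curve = cost_curve,
                 optimized = optimized),
            class = "sde_result")
}
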
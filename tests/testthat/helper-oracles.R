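# Independent brute-force oracles used to freeze expected values.

# O(N^2) double-loop MSD evaluated directly from the defining sum, with
# gap handling by pair-wise validity. Completely independent of
# compute_msd()'s vectorized path.
msd_oracle <- function(traj, max_lag = NULL) {
  tau <- attr(traj, "frame_interval")
  span <- traj$frame[nrow(traj)] - traj$frame[1]
  L <- span + 1L
  xs <- rep(NA_real_, L)
  ys <- rep(NA_real_, L)
  xs[traj$frame - traj$frame[1] + 1L] <- traj$x
  ys[traj$frame - traj$frame[1] + 1L] <- traj$y
  lags <- seq_len(if (is.null(max_lag)) span else min(max_lag, span))
  out <- data.frame(lag = lags, lag_time = lags * tau, msd = NA_real_,
                    n_pairs = 0L)
  for (n in lags) {
    acc <- 0
    cnt <- 0L
    for (i in 1:(L - n)) {
      if (!is.na(xs[i]) && !is.na(xs[i + n])) {
        acc <- acc + (xs[i + n] - xs[i])^2 + (ys[i + n] - ys[i])^2
        cnt <- cnt + 1L
      }
    }
    out$n_pairs[out$lag == n] <- cnt
    out$msd[out$lag == n] <- if (cnt > 0) acc / cnt else NA_real_
  }
  out[out$n_pairs > 0L, ]
}

# Mann-Whitney U by direct pair counting (ties as 1/2).
u_oracle <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s
}

# random trajectory with optional gaps, for oracle comparisons
random_traj <- function(n, tau = 0.03, gap_frac = 0) {
  f <- seq_len(n) - 1L
  if (gap_frac > 0 && n > 4) {
    drop <- sample(2:(n - 1), floor(gap_frac * n))
    f <- setdiff(f, drop)
  }
  trajectory(f, cumsum(rnorm(length(f), 0, 0.05)),
             cumsum(rnorm(length(f), 0, 0.05)), frame_interval = tau)
}
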
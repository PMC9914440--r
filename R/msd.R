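#' Time-averaged mean squared displacement of a trajectory
#'
#' For a trajectory observed at frames `i = 1..N` with frame interval `tau`,
#' the MSD at lag `n` is
#' `MSD(n tau) = (1 / (N - n)) * sum_i [(x_{i+n} - x_i)^2 + (y_{i+n} - y_i)^2]`.
#' Tracks with gaps (blinked-off frames) contribute only the displacement
#' pairs whose two endpoints were both observed, and the divisor is the
#' number of valid pairs; lags with no valid pair are omitted.
#'
#' @param traj a [trajectory()] with >= 2 localizations.
#' @param max_lag optional cap on the lag index (defaults to the full span).
#' @return `data.frame` of class `msd_curve` with columns `lag` (index),
#'   `lag_time` (s), `msd` (um^2), `n_pairs`; attribute `frame_interval`.
#' @export
compute_msd <- function(traj, max_lag = NULL) {
  if (nrow(traj) < 2L) stop("trajectory needs >= 2 localizations")
  tau <- frame_interval_of(traj)
  span <- traj$frame[nrow(traj)] - traj$frame[1]
  L <- span + 1L
  xs <- rep(NA_real_, L)
  ys <- rep(NA_real_, L)
  idx <- traj$frame - traj$frame[1] + 1L
  xs[idx] <- traj$x
  ys[idx] <- traj$y
  lags <- seq_len(if (is.null(max_lag)) span else min(max_lag, span))
  msd <- numeric(length(lags))
  np <- integer(length(lags))
  for (k in seq_along(lags)) {
    n <- lags[k]
    dx <- xs[(1L + n):L] - xs[1L:(L - n)]
    dy <- ys[(1L + n):L] - ys[1L:(L - n)]
    sq <- dx * dx + dy * dy
    ok <- !is.na(sq)
    np[k] <- sum(ok)
    msd[k] <- if (np[k]) sum(sq[ok]) / np[k] else NA_real_
  }
  keep <- np > 0L
  out <- data.frame(
    lag = lags[keep], lag_time = lags[keep] * tau,
    msd = msd[keep], n_pairs = np[keep]
  )
  attr(out, "frame_interval") <- tau
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the diffusion coefficient from the first MSD points
#'
#' Ordinary least squares through the first `n_points` MSD points (lags
#' `1..n_points`, default 4), excluding the (0, 0) origin:
#' `MSD(n tau) = 4 D n tau + b`. The slope gives `D = slope / 4` (2D
#' diffusion); the intercept `b` reflects the localization accuracy (for
#' independent noise of std `sigma` per axis its expectation is
#' `4 sigma^2`). Noise can make either estimate negative; such fits are
#' returned but flagged so callers can exclude them from log-scale
#' statistics.
#'
#' @param msd an [compute_msd()] curve containing lags `1..n_points`.
#' @param n_points number of initial lags to fit (default 4).
#' @return list of class `diffusion_estimate`: `D` (um^2/s), `intercept`
#'   (um^2), `n_points_fit`, `r_squared`, `valid` (all requested lags
#'   present), `nonpositive_D`.
#' @export
fit_diffusion <- function(msd, n_points = 4L) {
  rows <- match(seq_len(n_points), msd$lag)
  if (anyNA(rows)) {
    return(structure(
      list(D = NA_real_, intercept = NA_real_, n_points_fit = n_points,
           r_squared = NA_real_, valid = FALSE, nonpositive_D = NA),
      class = "diffusion_estimate"
    ))
  }
  t <- msd$lag_time[rows]
  y <- msd$msd[rows]
  fit <- lm(y ~ t)
  slope <- unname(coef(fit)[2])
  icpt <- unname(coef(fit)[1])
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(
      D = slope / 4, intercept = icpt, n_points_fit = as.integer(n_points),
      r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
      valid = TRUE, nonpositive_D = slope / 4 <= 0
    ),
    class = "diffusion_estimate"
  )
}

#' Explored area: the MSD value at fixed time lags
#'
#' The explored area (EA) of a trajectory is its MSD at configured lags,
#' default 0.42 s and 0.45 s (lag indices 14 and 15 at the 30 ms frame
#' interval); it is the confinement proxy reported alongside D. Each
#' requested lag must correspond to an integer lag index; lags beyond the
#' curve are returned as NA with a warning.
#'
#' @param msd an [compute_msd()] curve.
#' @param lags numeric lag times in seconds.
#' @return named numeric vector of EA values (um^2), names = lag seconds.
#' @export
explored_area <- function(msd, lags = c(0.42, 0.45)) {
  tau <- attr(msd, "frame_interval")
  if (is.null(tau)) stop("msd curve has no frame_interval attribute")
  idx <- lags / tau
  if (any(abs(idx - round(idx)) > 1e-6)) {
    stop("each EA lag must be an integer multiple of the frame interval")
  }
  idx <- as.integer(round(idx))
  rows <- match(idx, msd$lag)
  if (anyNA(rows)) {
    warning("EA lag(s) beyond the trajectory length omitted: ",
            paste(lags[is.na(rows)], collapse = ", "))
  }
  setNames(msd$msd[rows], format(lags))
}
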
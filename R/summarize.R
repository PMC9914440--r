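#' Per-trajectory metrics and per-condition population summary
#'
#' Computes, for every trajectory, the diffusion coefficient (first-four-lag
#' MSD fit), the explored area at the configured lags, and (when masks are
#' supplied) the compartment label; then summarises per condition and
#' compartment: median D, median EA (each trajectory contributes one EA
#' value per configured lag, so the EA sample size is `#QDs * #lags`),
#' trajectory counts, and the lag-wise mean MSD curve over the lags where at
#' least 80% of the trajectories are defined.
#'
#' Negative fitted D or intercepts are retained in the per-trajectory table
#' but counted in `n_nonpositive_D` so callers can exclude them from
#' log-scale statistics.
#'
#' @param trajs list of [trajectory()] objects.
#' @param masks optional named list of binary marker masks (see
#'   [classify_trajectory()]).
#' @param condition character scalar or vector (one per trajectory).
#' @param metadata optional `data.frame` with one row per trajectory
#'   (e.g. `culture`, `neuron`) carried into the tables for the stats layer.
#' @param pixel_size,inclusion_radius see [classify_trajectory()].
#' @param ea_lags EA lag times in seconds (default 0.42 and 0.45 s).
#' @param max_lag lag cap for the mean MSD curve (default 30).
#' @return list with `per_trajectory` (one row per trajectory), `summary`
#'   (one row per condition x compartment), `msd_mean` (per condition),
#'   and `counts` (exclusion bookkeeping).
#' @export
summarize_population <- function(trajs, masks = NULL, condition = "all",
                                 metadata = NULL, pixel_size = 190,
                                 inclusion_radius = 760,
                                 ea_lags = c(0.42, 0.45), max_lag = 30L) {
  n <- length(trajs)
  if (n < 1L) stop("at least one trajectory is required")
  condition <- rep_len(as.character(condition), n)
  curves <- lapply(trajs, compute_msd, max_lag = max_lag)
  fits <- lapply(curves, fit_diffusion)
  eas <- lapply(curves, function(m) {
    suppressWarnings(explored_area(m, ea_lags))
  })
  label <- rep("all", n)
  if (!is.null(masks)) {
    label <- vapply(
      trajs,
      function(tr) {
        classify_trajectory(tr, masks, pixel_size, inclusion_radius)[1]
      },
      character(1)
    )
  }
  per <- data.frame(
    particle_id = vapply(trajs, function(t) {
      as.integer(attr(t, "particle_id"))[1] %||% NA_integer_
    }, integer(1)),
    condition = condition,
    compartment = label,
    n_locs = vapply(trajs, nrow, integer(1)),
    D = vapply(fits, function(f) f$D, numeric(1)),
    intercept = vapply(fits, function(f) f$intercept, numeric(1)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1))
  )
  for (k in seq_along(ea_lags)) {
    per[[paste0("EA_", format(ea_lags[k]))]] <-
      vapply(eas, function(e) unname(e[k]), numeric(1))
  }
  if (!is.null(metadata)) {
    stopifnot(nrow(metadata) == n)
    per <- cbind(per, metadata)
  }

  ea_cols <- grep("^EA_", names(per), value = TRUE)
  groups <- unique(per[, c("condition", "compartment")])
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- per$condition == groups$condition[g] &
      per$compartment == groups$compartment[g]
    sub <- per[sel, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    ea_pool <- unlist(sub[, ea_cols], use.names = FALSE)
    data.frame(
      condition = groups$condition[g],
      compartment = groups$compartment[g],
      n_qds = nrow(sub),
      n_ea_values = sum(!is.na(ea_pool)),
      median_D = median(sub$D, na.rm = TRUE),
      median_EA = median(ea_pool, na.rm = TRUE),
      n_nonpositive_D = sum(sub$D <= 0, na.rm = TRUE)
    )
  })
  summary <- do.call(rbind, rows)

  # lag-wise ensemble mean MSD per condition (lags defined for >= 80% tracks)
  msd_mean <- do.call(rbind, lapply(unique(condition), function(cc) {
    sub <- curves[condition == cc]
    tau <- attr(sub[[1]], "frame_interval")
    lags <- sort(unique(unlist(lapply(sub, function(m) m$lag))))
    vals <- vapply(lags, function(l) {
      v <- vapply(sub, function(m) {
        i <- match(l, m$lag)
        if (is.na(i)) NA_real_ else m$msd[i]
      }, numeric(1))
      if (mean(!is.na(v)) >= 0.8) mean(v, na.rm = TRUE) else NA_real_
    }, numeric(1))
    keep <- !is.na(vals)
    if (!any(keep)) return(NULL)
    data.frame(condition = cc, lag = lags[keep],
               lag_time = lags[keep] * tau, mean_msd = vals[keep])
  }))

  list(
    per_trajectory = per, summary = summary, msd_mean = msd_mean,
    counts = list(
      n_trajectories = n,
      n_invalid_fit = sum(!vapply(fits, function(f) f$valid, logical(1))),
      n_nonpositive_D = sum(per$D <= 0, na.rm = TRUE),
      n_unclassified = sum(label == "unclassified")
    )
  )
}
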
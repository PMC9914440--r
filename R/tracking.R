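#' Link frame-stamped localizations into trajectories
#'
#' Frame-by-frame globally optimal assignment: for each frame, open tracks
#' are matched to the frame's detections by minimising the total squared
#' displacement (Hungarian assignment); displacements larger than `max_jump`
#' are forbidden. A track survives up to `max_gap` consecutive missing frames
#' (e.g. quantum-dot blinking) before it is closed; detections that match no
#' open track start new tracks, so every input localization belongs to
#' exactly one track.
#'
#' The default `max_jump` is five times the RMS frame-to-frame step of a
#' fast-diffusing particle, `5 * sqrt(4 * D_max * dt)` with
#' `D_max = 1 um^2/s`.
#'
#' @param locs `data.frame` with columns `frame`, `x`, `y` (um) and
#'   optionally `intensity`.
#' @param max_jump maximum frame-to-frame displacement in um (> 0).
#' @param max_gap maximum number of skipped frames bridged by a track (>= 0).
#' @param frame_interval seconds per frame, stored on the output
#'   trajectories.
#' @return list of [trajectory()] objects (singleton tracks included, so the
#'   localization count is conserved).
#' @export
link_localizations <- function(locs,
                               max_jump = 5 * sqrt(4 * 1 * frame_interval),
                               max_gap = 3L,
                               frame_interval = 0.030) {
  if (is.null(locs) || nrow(locs) == 0L) return(list())
  stopifnot(all(c("frame", "x", "y") %in% names(locs)),
            max_jump > 0, max_gap >= 0)
  big <- 4 * max_jump^2 + 1 # > any admissible block total, forbids a link
  frames <- sort(unique(locs$frame))
  # open track state
  id <- integer(0); last_x <- numeric(0); last_y <- numeric(0)
  last_f <- integer(0)
  rows_of <- list() # per track id: input row indices, in frame order
  next_id <- 1L
  for (f in frames) {
    det <- which(locs$frame == f)
    nd <- length(det)
    live <- which(last_f >= f - (max_gap + 1L))
    nt <- length(live)
    if (nt == 0L) {
      for (r in det) {
        rows_of[[next_id]] <- r
        id <- c(id, next_id); last_x <- c(last_x, locs$x[r])
        last_y <- c(last_y, locs$y[r]); last_f <- c(last_f, f)
        next_id <- next_id + 1L
      }
      next
    }
    # gated cost blocks: [link, track-skip; new-track, zeros]
    dx <- outer(last_x[live], locs$x[det], "-")
    dy <- outer(last_y[live], locs$y[det], "-")
    link <- dx^2 + dy^2
    link[link > max_jump^2] <- big
    gate <- max_jump^2
    n <- nt + nd
    cost <- matrix(0, n, n)
    cost[seq_len(nt), seq_len(nd)] <- link
    skip <- matrix(big, nt, nt); diag(skip) <- gate
    cost[seq_len(nt), nd + seq_len(nt)] <- skip
    newt <- matrix(big, nd, nd); diag(newt) <- gate
    cost[nt + seq_len(nd), seq_len(nd)] <- newt
    m <- solve_lap(cost)
    linked <- integer(0)
    for (k in seq_len(nt)) {
      j <- m[k]
      if (j <= nd && link[k, j] < big) { # track live[k] takes detection j
        r <- det[j]
        tid <- id[live[k]]
        rows_of[[tid]] <- c(rows_of[[tid]], r)
        last_x[live[k]] <- locs$x[r]
        last_y[live[k]] <- locs$y[r]
        last_f[live[k]] <- f
        linked <- c(linked, j)
      }
    }
    for (j in setdiff(seq_len(nd), linked)) {
      r <- det[j]
      rows_of[[next_id]] <- r
      id <- c(id, next_id); last_x <- c(last_x, locs$x[r])
      last_y <- c(last_y, locs$y[r]); last_f <- c(last_f, f)
      next_id <- next_id + 1L
    }
  }
  lapply(seq_along(rows_of), function(tid) {
    r <- rows_of[[tid]]
    trajectory(locs$frame[r], locs$x[r], locs$y[r],
               frame_interval = frame_interval, particle_id = tid)
  })
}

#' Remove pairs of trajectories that cross
#'
#' Two quantum dots passing within `crossing_radius` of each other in the
#' same frame can swap identities during linking, so both members of any
#' such pair are removed from the analysis. The default radius (0.5 um) is a
#' declared preprocessing parameter, not a reconstruction of the original
#' pipeline's value.
#'
#' @param trajs list of [trajectory()] objects.
#' @param crossing_radius distance in um below which two simultaneous
#'   localizations count as a crossing (> 0).
#' @return list with `kept` and `removed` (disjoint; union = input).
#' @export
remove_crossing_tracks <- function(trajs, crossing_radius = 0.5) {
  stopifnot(crossing_radius > 0)
  n <- length(trajs)
  bad <- logical(n)
  if (n >= 2L) {
    # bounding-box prefilter: pairs whose boxes are separated by more than
    # the crossing radius cannot cross
    x0 <- vapply(trajs, function(t) min(t$x), numeric(1))
    x1 <- vapply(trajs, function(t) max(t$x), numeric(1))
    y0 <- vapply(trajs, function(t) min(t$y), numeric(1))
    y1 <- vapply(trajs, function(t) max(t$y), numeric(1))
    for (a in seq_len(n - 1L)) {
      bs <- seq.int(a + 1L, n)
      near <- bs[x0[bs] - x1[a] < crossing_radius &
                   x0[a] - x1[bs] < crossing_radius &
                   y0[bs] - y1[a] < crossing_radius &
                   y0[a] - y1[bs] < crossing_radius]
      for (b in near) {
        ta <- trajs[[a]]; tb <- trajs[[b]]
        common <- intersect(ta$frame, tb$frame)
        if (!length(common)) next
        ia <- match(common, ta$frame)
        ib <- match(common, tb$frame)
        d2 <- (ta$x[ia] - tb$x[ib])^2 + (ta$y[ia] - tb$y[ib])^2
        if (any(d2 < crossing_radius^2)) bad[a] <- bad[b] <- TRUE
      }
    }
  }
  list(kept = trajs[!bad], removed = trajs[bad])
}
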
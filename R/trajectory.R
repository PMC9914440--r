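#' Construct a single-particle trajectory
#'
#' A trajectory is the unit of SPT analysis: the time-ordered 2D positions of
#' one particle. Positions are in micrometres; frames are 0-based acquisition
#' indices and must be strictly increasing (missing frames are gaps, e.g.
#' from quantum-dot blinking, and are skipped when averaging displacement
#' pairs).
#'
#' @param frame integer vector of 0-based frame indices, strictly increasing.
#' @param x,y numeric positions in micrometres.
#' @param frame_interval acquisition frame interval in seconds (default 0.030,
#'   the 30 ms integration time of the quantum-dot movies this package
#'   targets).
#' @param particle_id optional identifier kept through linking and reporting.
#' @return a `data.frame` of class `spt_trajectory` with columns
#'   `frame`, `x`, `y` and attributes `frame_interval`, `particle_id`.
#' @export
trajectory <- function(frame, x, y, frame_interval = 0.030, particle_id = NA) {
  frame <- as.integer(frame)
  stopifnot(length(frame) == length(x), length(x) == length(y))
  if (length(frame) < 1L) stop("trajectory needs at least one localization")
  if (any(frame < 0L)) stop("frames must be >= 0")
  if (is.unsorted(frame, strictly = TRUE)) {
    stop("frames must be strictly increasing")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("coordinates must be finite")
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0")
  }
  out <- data.frame(frame = frame, x = as.numeric(x), y = as.numeric(y))
  attr(out, "frame_interval") <- frame_interval
  attr(out, "particle_id") <- particle_id
  class(out) <- c("spt_trajectory", "data.frame")
  out
}

#' @export
print.spt_trajectory <- function(x, ...) {
  cat(sprintf(
    "<spt_trajectory> id=%s, %d localizations, frames %d..%d, tau=%g s\n",
    format(attr(x, "particle_id")), nrow(x), x$frame[1],
    x$frame[nrow(x)], attr(x, "frame_interval")
  ))
  print(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

frame_interval_of <- function(traj) {
  fi <- attr(traj, "frame_interval")
  if (is.null(fi)) stop("trajectory has no frame_interval attribute")
  fi
}

# Missing frames between first and last observed frame (blinking gaps).
gap_frames <- function(traj) {
  setdiff(seq(traj$frame[1], traj$frame[nrow(traj)]), traj$frame)
}
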
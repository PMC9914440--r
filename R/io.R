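#' Write a localization table to CSV
#'
#' Canonical CSV dialect: columns `track_id` (optional), `frame`, `x_nm`,
#' `y_nm`, `intensity` (optional). Coordinates are always stored in
#' nanometres regardless of the in-memory unit system.
#'
#' @param locs `data.frame` with columns `frame`, `x`, `y` and optionally
#'   `track_id`, `intensity`.
#' @param path output file.
#' @param unit unit of the in-memory `x`/`y` columns: `"nm"` or `"um"`.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  f <- if (unit == "um") um_to_nm else identity
  out <- data.frame(frame = locs$frame, x_nm = f(locs$x), y_nm = f(locs$y))
  if (!is.null(locs$track_id)) out <- cbind(track_id = locs$track_id, out)
  if (!is.null(locs$intensity)) out$intensity <- locs$intensity
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a localization table from CSV
#'
#' Accepts the canonical dialect of [write_localizations()] as well as
#' ThunderSTORM-style headers (`"frame"`, `"x [nm]"`, `"y [nm]"`, ...).
#'
#' @param path CSV file.
#' @return `data.frame` with columns `frame`, `x`, `y` (nm) and any of
#'   `track_id`, `intensity` present in the file.
#' @export
read_localizations <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  nm <- trimws(gsub("\"", "", names(d)))
  canon <- c(
    "frame" = "frame", "x_nm" = "x", "y_nm" = "y",
    "x [nm]" = "x", "y [nm]" = "y", "x" = "x", "y" = "y",
    "track_id" = "track_id", "id" = "track_id",
    "intensity" = "intensity", "intensity [photon]" = "intensity"
  )
  hit <- canon[nm]
  keep <- !is.na(hit)
  d <- d[, keep, drop = FALSE]
  names(d) <- hit[keep]
  if (!all(c("frame", "x", "y") %in% names(d))) {
    stop("localization CSV must provide frame, x and y columns")
  }
  d
}

#' Write trajectories to CSV / read them back
#'
#' One row per localization with a `track_id` column; coordinates in nm.
#'
#' @param trajs list of [trajectory()] objects.
#' @param path CSV file.
#' @return `path` invisibly (writer); list of trajectories (reader).
#' @export
write_trajectories <- function(trajs, path) {
  rows <- do.call(rbind, lapply(seq_along(trajs), function(k) {
    tr <- trajs[[k]]
    data.frame(
      track_id = attr(tr, "particle_id") %||% k,
      frame = tr$frame, x_nm = um_to_nm(tr$x), y_nm = um_to_nm(tr$y)
    )
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @param frame_interval seconds per frame for the reconstructed
#'   trajectories.
#' @rdname write_trajectories
#' @export
read_trajectories <- function(path, frame_interval = 0.030) {
  d <- read_localizations(path)
  if (is.null(d$track_id)) stop("trajectory CSV needs a track_id column")
  lapply(split(d, d$track_id), function(s) {
    s <- s[order(s$frame), ]
    trajectory(s$frame, nm_to_um(s$x), nm_to_um(s$y),
               frame_interval = frame_interval,
               particle_id = s$track_id[1])
  })
}

#' Write / read a single-channel image as TIFF
#'
#' Masks are stored as 0/1, images as 16-bit (counts) or 32-bit float.
#'
#' @param img numeric/logical matrix.
#' @param path TIFF file.
#' @param bits 8, 16 (integer counts, scaled by `2^bits - 1` on disk) or
#'   32 (float, stored as-is).
#' @return `path` invisibly (writer); numeric matrix (reader).
#' @export
write_image_tiff <- function(img, path, bits = 16L) {
  m <- img * 1.0
  if (bits %in% c(8L, 16L)) {
    top <- 2^bits - 1
    if (any(m < 0 | m > top)) stop("image values exceed the bit depth")
    tiff::writeTIFF(m / top, path, bits.per.sample = bits)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, bits = 16L) {
  m <- tiff::readTIFF(path)
  if (bits %in% c(8L, 16L)) m <- round(m * (2^bits - 1))
  m
}

#' Write simulation ground truth as a JSON sidecar
#'
#' Serializes the `truth` element returned by the simulators (true paths or
#' emitter positions, compartment labels, per-frame drift) next to the
#' emitted data files, so recovery analyses can be scored offline.
#'
#' @param truth a ground-truth list from [simulate_trajectory()],
#'   [simulate_scene()], [simulate_storm()] or [simulate_widefield()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  truth$config <- NULL # configs carry functions-free lists; keep data only
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML (nestable key/value) file; returned as a named list. See
#' [run_pipeline()] for the recognised fields.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
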
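#' Configuration for a simulated STORM detection stream
#'
#' Defaults match the targeted acquisition: 30,000 frames at a 50 ms frame
#' interval. Emitters are laid out in disc-shaped clusters (uniform within
#' each disc) plus an optional uniform background over `field`. Each emitter
#' blinks in temporally clustered bursts: the number of bursts is
#' Poisson(`mean_bursts`), each burst starts at a uniform random frame and
#' lasts Geometric frames with mean `mean_burst_len`, and every burst frame
#' yields one detection at the emitter position plus isotropic Gaussian
#' localization jitter and the stage drift of that frame.
#'
#' Drift models: `none`; `linear` with `drift_rate` (nm/frame, per axis, so
#' the offset at frame f is `f * drift_rate`); `random_walk` with per-frame
#' Gaussian steps of std `drift_sd` (nm).
#'
#' @param n_frames number of acquisition frames (>= 1).
#' @param frame_interval seconds per frame.
#' @param clusters `data.frame` with columns `cx`, `cy`, `radius` (nm) and
#'   `n_emitters`; may be NULL.
#' @param background_density background emitters per um^2 over `field` (>= 0).
#' @param field numeric length-4 `c(xmin, xmax, ymin, ymax)` in nm bounding
#'   the background emitters (defaults to a 2 x 2 um field).
#' @param mean_bursts mean number of blinking bursts per emitter.
#' @param mean_burst_len mean burst length in frames (>= 1).
#' @param localization_sigma localization jitter std in nm.
#' @param drift_model `"none"`, `"linear"` or `"random_walk"`.
#' @param drift_rate numeric length-2, nm per frame (linear model).
#' @param drift_sd per-frame random-walk step std in nm.
#' @param seed optional integer seed.
#' @return a list of class `storm_sim_config`.
#' @export
storm_sim_config <- function(n_frames = 30000L,
                             frame_interval = 0.050,
                             clusters = NULL,
                             background_density = 0,
                             field = c(0, 2000, 0, 2000),
                             mean_bursts = 3,
                             mean_burst_len = 3,
                             localization_sigma = 10,
                             drift_model = c("none", "linear", "random_walk"),
                             drift_rate = c(0, 0),
                             drift_sd = 0,
                             seed = NULL) {
  drift_model <- match.arg(drift_model)
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (background_density < 0) stop("background_density must be >= 0")
  if (localization_sigma < 0) stop("localization_sigma must be >= 0")
  if (mean_bursts < 0 || mean_burst_len < 1) {
    stop("mean_bursts must be >= 0 and mean_burst_len >= 1")
  }
  if (!is.null(clusters)) {
    stopifnot(all(c("cx", "cy", "radius", "n_emitters") %in% names(clusters)))
    if (any(clusters$radius <= 0)) stop("cluster radii must be > 0")
    if (any(clusters$n_emitters < 0)) stop("emitter counts must be >= 0")
  }
  structure(
    list(
      n_frames = as.integer(n_frames), frame_interval = frame_interval,
      clusters = clusters, background_density = background_density,
      field = field, mean_bursts = mean_bursts,
      mean_burst_len = mean_burst_len,
      localization_sigma = localization_sigma,
      drift_model = drift_model, drift_rate = drift_rate,
      drift_sd = drift_sd, seed = seed
    ),
    class = "storm_sim_config"
  )
}

#' Simulate a STORM detection table
#'
#' @param cfg a [storm_sim_config()].
#' @return list with `detections` (a [detection_table()]: `frame`, `x`, `y`
#'   in nm, plus an `emitter` column giving the true emitter of each
#'   detection) and `truth` (list: `emitters` data.frame with true positions
#'   and cluster membership, `true_drift` per-frame data.frame, `config`).
#' @export
simulate_storm <- function(cfg) {
  stopifnot(inherits(cfg, "storm_sim_config"))
  .local_seed(cfg$seed)
  n_frames <- cfg$n_frames

  # emitter positions
  ex <- numeric(0); ey <- numeric(0); label <- integer(0)
  if (!is.null(cfg$clusters)) {
    for (k in seq_len(nrow(cfg$clusters))) {
      cl <- cfg$clusters[k, ]
      ne <- cl$n_emitters
      th <- runif(ne, 0, 2 * pi)
      rr <- cl$radius * sqrt(runif(ne))
      ex <- c(ex, cl$cx + rr * cos(th))
      ey <- c(ey, cl$cy + rr * sin(th))
      label <- c(label, rep.int(k, ne))
    }
  }
  if (cfg$background_density > 0) {
    area_um2 <- (cfg$field[2] - cfg$field[1]) *
      (cfg$field[4] - cfg$field[3]) / 1e6
    nb <- rpois(1, cfg$background_density * area_um2)
    ex <- c(ex, runif(nb, cfg$field[1], cfg$field[2]))
    ey <- c(ey, runif(nb, cfg$field[3], cfg$field[4]))
    label <- c(label, rep.int(0L, nb))
  }
  n_em <- length(ex)

  # drift trajectory (per frame, nm)
  fr_all <- seq_len(n_frames) - 1L
  drift <- switch(cfg$drift_model,
    none = cbind(0 * fr_all, 0 * fr_all),
    linear = cbind(fr_all * cfg$drift_rate[1], fr_all * cfg$drift_rate[2]),
    random_walk = cbind(
      cumsum(c(0, rnorm(n_frames - 1L, 0, cfg$drift_sd))),
      cumsum(c(0, rnorm(n_frames - 1L, 0, cfg$drift_sd)))
    )
  )

  # blinking bursts -> detection frames per emitter
  frames <- integer(0); emitter <- integer(0)
  for (e in seq_len(n_em)) {
    nb <- rpois(1, cfg$mean_bursts)
    if (nb == 0) next
    starts <- sample.int(n_frames, nb, replace = TRUE) - 1L
    lens <- 1L + rgeom(nb, 1 / cfg$mean_burst_len)
    f <- unlist(lapply(seq_len(nb), function(b) {
      seq.int(starts[b], min(starts[b] + lens[b] - 1L, n_frames - 1L))
    }))
    f <- sort(unique(f))
    frames <- c(frames, f)
    emitter <- c(emitter, rep.int(e, length(f)))
  }
  ord <- order(frames, emitter)
  frames <- frames[ord]; emitter <- emitter[ord]
  nd <- length(frames)
  x <- ex[emitter] + rnorm(nd, 0, cfg$localization_sigma) +
    drift[frames + 1L, 1]
  y <- ey[emitter] + rnorm(nd, 0, cfg$localization_sigma) +
    drift[frames + 1L, 2]
  dets <- detection_table(frames, x, y,
    frame_interval = cfg$frame_interval, n_frames = n_frames
  )
  dets$emitter <- emitter
  list(
    detections = dets,
    truth = list(
      emitters = data.frame(id = seq_len(n_em), x = ex, y = ey,
                            cluster = label),
      true_drift = data.frame(frame = fr_all, dx = drift[, 1],
                              dy = drift[, 2]),
      config = cfg
    )
  )
}

#' Construct a STORM detection table
#'
#' Frame-stamped single-molecule localizations in nanometres, the input of
#' the drift-correction / merging / rendering chain.
#'
#' @param frame integer 0-based frame indices.
#' @param x,y coordinates in nm.
#' @param frame_interval seconds per frame (default 0.050).
#' @param n_frames total acquisition length (default `max(frame) + 1`).
#' @return `data.frame` of class `detection_table`.
#' @export
detection_table <- function(frame, x, y, frame_interval = 0.050,
                            n_frames = NULL) {
  frame <- as.integer(frame)
  stopifnot(length(frame) == length(x), length(x) == length(y))
  if (length(frame) && any(frame < 0L)) stop("frames must be >= 0")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("coordinates must be finite")
  }
  if (is.null(n_frames)) {
    n_frames <- if (length(frame)) max(frame) + 1L else 0L
  }
  if (length(frame) && any(frame >= n_frames)) {
    stop("frames must lie in [0, n_frames)")
  }
  out <- data.frame(frame = frame, x = as.numeric(x), y = as.numeric(y))
  attr(out, "frame_interval") <- frame_interval
  attr(out, "n_frames") <- as.integer(n_frames)
  class(out) <- c("detection_table", "data.frame")
  out
}

#' Simulate a widefield punctate image
#'
#' Image = smooth background (constant plus optional linear gradient) +
#' isotropic Gaussian puncta + Gaussian read-out noise, quantized to the
#' 16-bit camera range. Ground truth lists the planted puncta.
#'
#' @param puncta `data.frame` with columns `x`, `y` (pixel coordinates,
#'   0-based, must lie inside the image), `sigma` (px) and `amplitude`
#'   (counts); NULL or empty for none.
#' @param background_level constant background in counts.
#' @param noise_sigma Gaussian noise std in counts.
#' @param shape integer length-2 image size in pixels (default 512 x 512,
#'   the acquisition frame size).
#' @param gradient numeric length-2 background slope in counts/px per axis.
#' @param seed optional integer seed.
#' @return list with `image` (integer matrix, 16-bit range) and `truth`.
#' @export
simulate_widefield <- function(puncta = NULL, background_level = 100,
                               noise_sigma = 0, shape = c(512L, 512L),
                               gradient = c(0, 0), seed = NULL) {
  .local_seed(seed)
  nx <- shape[1]; ny <- shape[2]
  xs <- seq_len(nx) - 1L
  ys <- seq_len(ny) - 1L
  img <- background_level + outer(xs * gradient[1], ys * gradient[2], "+")
  if (!is.null(puncta) && nrow(puncta)) {
    ok <- puncta$x >= 0 & puncta$x <= nx - 1 &
      puncta$y >= 0 & puncta$y <= ny - 1
    if (!all(ok)) stop("puncta must lie inside the image")
    for (k in seq_len(nrow(puncta))) {
      gx <- exp(-(xs - puncta$x[k])^2 / (2 * puncta$sigma[k]^2))
      gy <- exp(-(ys - puncta$y[k])^2 / (2 * puncta$sigma[k]^2))
      img <- img + puncta$amplitude[k] * outer(gx, gy)
    }
  }
  if (noise_sigma > 0) {
    img <- img + matrix(rnorm(nx * ny, 0, noise_sigma), nx, ny)
  }
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 65535L)), nx, ny)
  list(image = img, truth = list(puncta = puncta,
                                 background_level = background_level))
}
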
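#' Estimate stage drift from sliding-window centers of mass
#'
#' Partial reconstructions of `window_size` frames (default 2000) are taken
#' every `window_step` frames; the center of mass of the detections in each
#' window, relative to the first usable window, gives the drift at the
#' window's mean detection frame. A per-frame trace is obtained by linear
#' interpolation between windows and linear extrapolation beyond the first
#' and last window (continuing the adjacent segment's slope), so a linear
#' drift is recovered exactly over the whole acquisition. Windows with fewer
#' than 10 detections are skipped and bridged by the interpolation.
#'
#' By default all detections contribute (appropriate when the field is
#' dominated by the cluster being followed); `roi = c(xmin, xmax, ymin,
#' ymax)` (nm) restricts the estimate to one cluster's neighbourhood, and
#' [densest_roi()] proposes such a box.
#'
#' @param dets a [detection_table()] (nm).
#' @param window_size window length in frames (default 2000).
#' @param window_step step between window starts in frames (default 500).
#' @param roi optional numeric length-4 box in nm.
#' @param n_frames acquisition length (defaults to the table's attribute).
#' @return `data.frame` of class `drift_trace` with columns `frame`, `dx`,
#'   `dy` (nm); `dx = dy = 0` over the reference (first) window.
#' @export
estimate_drift <- function(dets, window_size = 2000L, window_step = 500L,
                           roi = NULL, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- attr(dets, "n_frames") %||%
      (max(dets$frame) + 1L)
  stopifnot(window_size >= 1L, window_step >= 1L)
  if (window_size > n_frames) stop("window_size exceeds n_frames")
  d <- dets
  if (!is.null(roi)) {
    keep <- d$x >= roi[1] & d$x <= roi[2] & d$y >= roi[3] & d$y <= roi[4]
    d <- d[keep, , drop = FALSE]
  }
  if (nrow(d) == 0L) stop("no detections available for drift estimation")
  starts <- seq.int(0L, n_frames - window_size, by = window_step)
  if (starts[length(starts)] != n_frames - window_size) {
    starts <- c(starts, n_frames - window_size)
  }
  cx <- numeric(0); cy <- numeric(0); at <- numeric(0)
  for (s in starts) {
    w <- d$frame >= s & d$frame < s + window_size
    if (sum(w) < 10L) next # too few detections: window skipped
    cx <- c(cx, mean(d$x[w]))
    cy <- c(cy, mean(d$y[w]))
    at <- c(at, mean(d$frame[w]))
  }
  if (length(at) == 0L) stop("all drift windows are empty")
  cx <- cx - cx[1]
  cy <- cy - cy[1]
  fr <- seq_len(n_frames) - 1L
  interp <- function(v) {
    if (length(at) == 1L) return(rep(v, n_frames))
    out <- approx(at, v, xout = fr, rule = 2)$y
    # linear extrapolation beyond the first/last window center
    s1 <- (v[2] - v[1]) / (at[2] - at[1])
    k <- length(at)
    s2 <- (v[k] - v[k - 1]) / (at[k] - at[k - 1])
    lo <- fr < at[1]
    hi <- fr > at[k]
    out[lo] <- v[1] + s1 * (fr[lo] - at[1])
    out[hi] <- v[k] + s2 * (fr[hi] - at[k])
    out
  }
  out <- data.frame(frame = fr, dx = interp(cx), dy = interp(cy))
  class(out) <- c("drift_trace", "data.frame")
  out
}

#' Densest region of a detection table
#'
#' Finds the `box` x `box` nm bin (default 500 nm) containing the most
#' detections; a convenience ROI for [estimate_drift()] on multi-cluster
#' fields with modest drift.
#'
#' @param dets a [detection_table()].
#' @param box box side in nm.
#' @return numeric length-4 `c(xmin, xmax, ymin, ymax)`.
#' @export
densest_roi <- function(dets, box = 500) {
  ix <- floor(dets$x / box)
  iy <- floor(dets$y / box)
  key <- paste(ix, iy)
  top <- names(which.max(table(key)))
  ij <- as.numeric(strsplit(top, " ")[[1]])
  c(ij[1] * box, (ij[1] + 1) * box, ij[2] * box, (ij[2] + 1) * box)
}

#' Apply (subtract) a drift trace from a detection table
#'
#' `x' = x - dx(frame)`, `y' = y - dy(frame)`; the row count is unchanged.
#'
#' @param dets a [detection_table()].
#' @param trace a [estimate_drift()] trace defined on all frames present.
#' @return drift-corrected [detection_table()].
#' @export
apply_drift <- function(dets, trace) {
  i <- match(dets$frame, trace$frame)
  if (anyNA(i)) stop("drift trace does not cover all detection frames")
  out <- dets
  out$x <- dets$x - trace$dx[i]
  out$y <- dets$y - trace$dy[i]
  out
}

#' Merge repeated detections of the same molecule
#'
#' A fluorophore blinking across frames yields trains of detections at
#' nearly the same position. Detections are swept in frame order; a
#' detection joins an open molecule when it falls within `2 * sigma` of the
#' molecule's running mean position and within `time_window` seconds of the
#' molecule's last detection (transitive chaining, supporting long blinking
#' trains); otherwise it opens a new molecule. Defaults: `sigma` 25 nm
#' (spatial radius 50 nm) and 15 s.
#'
#' @param dets a [detection_table()] (nm).
#' @param sigma localization accuracy in nm (> 0); merge radius is
#'   `2 * sigma`.
#' @param time_window maximum temporal gap within one molecule, seconds.
#' @param frame_interval seconds per frame (defaults to the table's
#'   attribute).
#' @return `data.frame` of class `molecule_table`: `x`, `y` (mean of member
#'   detections), `n_detections`, `first_frame`, `last_frame`. The
#'   detection counts sum to the input row count.
#' @export
merge_detections <- function(dets, sigma = 25, time_window = 15,
                             frame_interval = NULL) {
  stopifnot(sigma > 0, time_window >= 0)
  if (is.null(frame_interval)) {
    frame_interval <- attr(dets, "frame_interval") %||% 0.050
  }
  gap_frames <- time_window / frame_interval
  r2 <- (2 * sigma)^2
  o <- order(dets$frame)
  fx <- dets$x[o]; fy <- dets$y[o]; ff <- dets$frame[o]
  n <- length(fx)
  # molecule state (grows as needed)
  mx <- numeric(0); my <- numeric(0); mn <- integer(0)
  mf0 <- integer(0); mf1 <- integer(0)
  open <- integer(0) # indices of molecules still accepting detections
  for (i in seq_len(n)) {
    if (length(open)) {
      # close molecules whose last detection is too old
      open <- open[ff[i] - mf1[open] <= gap_frames]
    }
    j <- 0L
    if (length(open)) {
      d2 <- (mx[open] - fx[i])^2 + (my[open] - fy[i])^2
      k <- which.min(d2)
      if (d2[k] <= r2) j <- open[k]
    }
    if (j > 0L) {
      mx[j] <- (mx[j] * mn[j] + fx[i]) / (mn[j] + 1L)
      my[j] <- (my[j] * mn[j] + fy[i]) / (mn[j] + 1L)
      mn[j] <- mn[j] + 1L
      mf1[j] <- ff[i]
    } else {
      mx <- c(mx, fx[i]); my <- c(my, fy[i]); mn <- c(mn, 1L)
      mf0 <- c(mf0, ff[i]); mf1 <- c(mf1, ff[i])
      open <- c(open, length(mx))
    }
  }
  out <- data.frame(
    x = mx, y = my, n_detections = mn,
    first_frame = mf0, last_frame = mf1
  )
  class(out) <- c("molecule_table", "data.frame")
  out
}

#' Render detections into a 2D count image
#'
#' Superimposes detection coordinates on a pixel grid (default 20 nm): the
#' value of pixel (i, j) (0-based, origin at `origin` nm) is the number of
#' detections with `floor((x - origin) / pixel_size) == i` (and likewise in
#' y). Bounds default to the data extent padded by one pixel, so the pixel
#' counts always sum to the number of detections.
#'
#' @param dets a [detection_table()] (nm), non-empty.
#' @param pixel_size rendering pixel size in nm (default 20).
#' @param origin optional numeric length-2 lower-left corner (nm); snapped
#'   convention is that `origin` is the corner of pixel (0, 0).
#' @return list of class `storm_render`: `counts` (matrix, x along rows),
#'   `pixel_size`, `origin`.
#' @export
render_detections <- function(dets, pixel_size = 20, origin = NULL) {
  stopifnot(pixel_size > 0)
  if (nrow(dets) == 0L) stop("cannot render an empty detection table")
  if (is.null(origin)) {
    origin <- c(
      (floor(min(dets$x) / pixel_size) - 1) * pixel_size,
      (floor(min(dets$y) / pixel_size) - 1) * pixel_size
    )
  }
  ix <- floor((dets$x - origin[1]) / pixel_size)
  iy <- floor((dets$y - origin[2]) / pixel_size)
  if (any(ix < 0) || any(iy < 0)) stop("origin lies above some detections")
  nx <- max(ix) + 2L
  ny <- max(iy) + 2L
  counts <- matrix(0L, nx, ny)
  tab <- table(factor(ix + nx * iy, levels = 0:(nx * ny - 1L)))
  counts[] <- as.integer(tab)
  structure(
    list(counts = counts, pixel_size = pixel_size, origin = origin),
    class = "storm_render"
  )
}

# 4- or 8-connected component labelling of a logical matrix (igraph).
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nx <- nrow(mask); ny <- ncol(mask)
  on <- which(mask)
  lab <- matrix(0L, nx, ny)
  if (!length(on)) return(lab)
  id <- match(seq_len(nx * ny), on) # pixel linear index -> vertex id
  edges <- integer(0)
  add_pairs <- function(a, b) {
    ok <- !is.na(id[a]) & !is.na(id[b])
    c(rbind(id[a[ok]], id[b[ok]]))
  }
  i <- ((on - 1L) %% nx) + 1L
  j <- ((on - 1L) %/% nx) + 1L
  right <- on[i < nx]
  down <- on[j < ny]
  edges <- c(
    add_pairs(right, right + 1L),
    add_pairs(down, down + nx)
  )
  if (connectivity == 8L) {
    dr <- on[i < nx & j < ny]
    ur <- on[i < nx & j > 1L]
    edges <- c(
      edges,
      add_pairs(dr, dr + 1L + nx),
      add_pairs(ur, ur + 1L - nx)
    )
  }
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lab[on] <- as.integer(comp)
  lab
}

#' Segment nanoclusters from a rendered detection image
#'
#' Density-threshold segmentation: pixels whose count reaches
#' `intensity_frac` (default 1%) of the maximum pixel count form the binary
#' image; its 8-connected components are candidate nanoclusters; a component
#' is kept when it holds at least `min_detections` detections (default 10)
#' and its detection density (detections / area) is at least `min_density`
#' (default 0.1 per nm^2). Area is the pixel count times the pixel area, and
#' `density * area = n_detections` exactly. Segmentation operates on raw
#' detections; molecule counts are attached afterwards from a
#' [merge_detections()] table when supplied.
#'
#' @param img a [render_detections()] image.
#' @param intensity_frac binarization threshold as a fraction of the maximum
#'   pixel count (default 0.01).
#' @param min_density minimum detections per nm^2 (default 0.1).
#' @param min_detections minimum detections per cluster (default 10).
#' @param connectivity 8 (default) or 4.
#' @param molecules optional [merge_detections()] table; adds `n_molecules`
#'   per cluster (molecules whose position falls on the cluster's pixels).
#' @return `data.frame` of class `nanocluster_table`: `cluster_id`,
#'   `n_pixels`, `area` (nm^2), `n_detections`, `density` (nm^-2) and
#'   optionally `n_molecules`; zero rows when nothing passes the thresholds.
#' @export
segment_nanoclusters <- function(img, intensity_frac = 0.01,
                                 min_density = 0.1, min_detections = 10L,
                                 connectivity = 8L, molecules = NULL) {
  counts <- img$counts
  ps <- img$pixel_size
  mx <- max(counts)
  empty <- data.frame(
    cluster_id = integer(0), n_pixels = integer(0), area = numeric(0),
    n_detections = integer(0), density = numeric(0)
  )
  if (mx <= 0) return(`class<-`(empty, c("nanocluster_table", "data.frame")))
  binary <- counts >= max(intensity_frac * mx, 1e-12) & counts > 0
  if (!any(binary)) {
    return(`class<-`(empty, c("nanocluster_table", "data.frame")))
  }
  lab <- label_components(binary, connectivity)
  ids <- sort(unique(lab[lab > 0L]))
  npix <- vapply(ids, function(k) sum(lab == k), integer(1))
  ndet <- vapply(ids, function(k) sum(counts[lab == k]), numeric(1))
  area <- npix * ps^2
  dens <- ndet / area
  keep <- ndet >= min_detections & dens >= min_density
  out <- data.frame(
    cluster_id = seq_len(sum(keep)),
    n_pixels = npix[keep], area = area[keep],
    n_detections = as.integer(ndet[keep]), density = dens[keep]
  )
  if (!is.null(molecules) && nrow(out)) {
    mix <- floor((molecules$x - img$origin[1]) / ps) + 1L
    miy <- floor((molecules$y - img$origin[2]) / ps) + 1L
    inb <- mix >= 1L & mix <= nrow(lab) & miy >= 1L & miy <= ncol(lab)
    mlab <- rep(0L, nrow(molecules))
    mlab[inb] <- lab[cbind(mix[inb], miy[inb])]
    kept_ids <- ids[keep]
    out$n_molecules <- vapply(
      kept_ids, function(k) sum(mlab == k), integer(1)
    )
  }
  class(out) <- c("nanocluster_table", "data.frame")
  out
}

#' Tabulate nanocluster metrics with experiment metadata
#'
#' One row per nanocluster with the three reported quantities (area,
#' detections per cluster, molecular density) tagged with
#' image/neuron/condition/culture metadata so rows can feed the clustered
#' resampling statistics directly.
#'
#' @param clusters a [segment_nanoclusters()] table.
#' @param metadata named list (e.g. `list(condition = "control",
#'   culture = 1, neuron = 3)`) recycled onto every row.
#' @return `data.frame`; zero rows in, zero rows out.
#' @export
cluster_report <- function(clusters, metadata = list()) {
  base <- as.data.frame(clusters)
  if (length(metadata)) {
    for (nm in names(metadata)) base[[nm]] <- metadata[[nm]]
  }
  base
}
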
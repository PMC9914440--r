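# Exact k x k median filter with replicate padding. k = 3 uses a
# median-of-9 selection network evaluated with vectorized pmin/pmax over
# whole shifted images; larger (odd) k falls back to per-pixel sorting.
median_filter <- function(img, k = 3L) {
  stopifnot(k %% 2L == 1L, k >= 1L)
  nx <- nrow(img); ny <- ncol(img)
  if (k > nx || k > ny) stop("kernel larger than image")
  if (k == 1L) return(img)
  h <- (k - 1L) %/% 2L
  pad <- img[
    pmin(pmax(seq_len(nx + 2L * h) - h, 1L), nx),
    pmin(pmax(seq_len(ny + 2L * h) - h, 1L), ny),
    drop = FALSE
  ]
  shifts <- vector("list", k * k)
  s <- 1L
  for (dx in 0:(k - 1L)) {
    for (dy in 0:(k - 1L)) {
      shifts[[s]] <- pad[dx + seq_len(nx), dy + seq_len(ny), drop = FALSE]
      s <- s + 1L
    }
  }
  if (k == 3L) {
    p <- shifts
    sw <- function(a, b) {
      lo <- pmin(p[[a]], p[[b]]); hi <- pmax(p[[a]], p[[b]])
      p[[a]] <<- lo; p[[b]] <<- hi
    }
    # median-of-9 selection network
    sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
    sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
    sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
    return(p[[5]])
  }
  stack <- matrix(unlist(shifts, use.names = FALSE), nx * ny, k * k)
  matrix(apply(stack, 1, median), nx, ny)
}

#' Flatten the image background for cluster detection
#'
#' Subtracts a local background estimate (the `kernel_size` x `kernel_size`
#' median filter of the image, replicate-padded at the borders) and clips at
#' zero. The flattened image sharpens cluster outlines and is used only to
#' *detect* clusters; all intensity measurements are taken on the raw image.
#'
#' @param img numeric matrix.
#' @param kernel_size odd window size (default 3).
#' @return numeric matrix, `pmax(img - median_filter(img), 0)`.
#' @export
flatten_background <- function(img, kernel_size = 3L) {
  if (kernel_size %% 2L != 1L) stop("kernel_size must be odd")
  pmax(img - median_filter(img, kernel_size), 0)
}

#' Segment fluorescence clusters inside a dendritic ROI
#'
#' Connected components (8-connectivity) of `flattened >= threshold` within
#' the ROI are the clusters; per cluster the area (pixels x pixel area) and
#' the mean intensity on the *raw* image are reported, plus the cluster
#' density (clusters per um^2 of ROI). The intensity threshold is a
#' user-defined per-experiment constant, mirroring acquisition batches
#' imaged at a fixed exposure; it is never auto-chosen.
#'
#' @param flattened output of [flatten_background()].
#' @param raw the raw image the flattened image was derived from.
#' @param roi logical matrix (TRUE inside the ROI); NULL = whole image.
#' @param threshold intensity threshold on the flattened image (> 0).
#' @param pixel_size camera pixel size in nm (default 190).
#' @return list of class `wf_cluster_set`: `clusters` (`data.frame`:
#'   `cluster_id`, `n_pixels`, `area_um2`, `mean_raw_intensity`),
#'   `n_clusters`, `roi_area_um2`, `density_per_um2`.
#' @export
segment_wf_clusters <- function(flattened, raw, roi = NULL, threshold,
                                pixel_size = 190) {
  stopifnot(threshold > 0, all(dim(flattened) == dim(raw)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(raw), ncol(raw))
  if (!any(roi)) stop("empty ROI")
  px_um2 <- (pixel_size / 1000)^2
  binary <- (flattened >= threshold) & roi
  lab <- label_components(binary, 8L)
  ids <- sort(unique(lab[lab > 0L]))
  clusters <- do.call(rbind, lapply(seq_along(ids), function(k) {
    sel <- lab == ids[k]
    data.frame(
      cluster_id = k, n_pixels = sum(sel),
      area_um2 = sum(sel) * px_um2,
      mean_raw_intensity = mean(raw[sel])
    )
  }))
  if (is.null(clusters)) {
    clusters <- data.frame(
      cluster_id = integer(0), n_pixels = integer(0),
      area_um2 = numeric(0), mean_raw_intensity = numeric(0)
    )
  }
  roi_area <- sum(roi) * px_um2
  structure(
    list(
      clusters = clusters, n_clusters = nrow(clusters),
      roi_area_um2 = roi_area,
      density_per_um2 = nrow(clusters) / roi_area
    ),
    class = "wf_cluster_set"
  )
}

#' Surface-to-total fluorescence ratio in an ROI
#'
#' Mean pixel intensity of the surface channel divided by the mean of the
#' total-pool channel over a common ROI of co-registered,
#' background-corrected images. Scale-invariant in any gain common to both
#' channels.
#'
#' @param surface_img,total_img numeric matrices of equal size.
#' @param roi logical matrix; NULL = whole image.
#' @return the ratio (scalar).
#' @export
surface_total_ratio <- function(surface_img, total_img, roi = NULL) {
  stopifnot(all(dim(surface_img) == dim(total_img)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(total_img), ncol(total_img))
  if (!any(roi)) stop("empty ROI")
  den <- mean(total_img[roi])
  if (den == 0) stop("total-channel mean is zero in the ROI")
  mean(surface_img[roi]) / den
}

#' Background-subtracted ratiometric trace
#'
#' For each timepoint of two co-acquired stacks (e.g. the two excitation
#' channels of a ratiometric chloride probe) the ratio
#' `(mean_num(roi) - mean_num(bg_roi)) / (mean_den(roi) - mean_den(bg_roi))`
#' is computed; frames whose background-subtracted denominator is <= 0 are
#' flagged invalid (NA ratio). Which channel is the numerator is the
#' caller's choice. The default acquisition cadence is one frame
#' every 30 s for 5 min (11 timepoints).
#'
#' @param num_stack,den_stack lists of matrices or 3D arrays (x, y, t) of
#'   equal length.
#' @param roi logical matrix over the cell; `bg_roi` a background region
#'   outside cells.
#' @param bg_roi logical matrix for background subtraction.
#' @param period seconds between timepoints (default 30).
#' @return `data.frame` of class `ratio_trace`: `t` (s), `ratio`, `valid`;
#'   attribute `mean_ratio` (mean over valid frames).
#' @export
ratiometric_trace <- function(num_stack, den_stack, roi, bg_roi,
                              period = 30) {
  as_list <- function(s) {
    if (is.list(s)) s
    else lapply(seq_len(dim(s)[3]), function(i) s[, , i])
  }
  num <- as_list(num_stack)
  den <- as_list(den_stack)
  if (length(num) != length(den)) stop("stacks must have equal length")
  ratio <- vapply(seq_along(num), function(i) {
    nv <- mean(num[[i]][roi]) - mean(num[[i]][bg_roi])
    dv <- mean(den[[i]][roi]) - mean(den[[i]][bg_roi])
    if (dv <= 0) NA_real_ else nv / dv
  }, numeric(1))
  out <- data.frame(
    t = (seq_along(num) - 1L) * period,
    ratio = ratio, valid = !is.na(ratio)
  )
  attr(out, "mean_ratio") <- mean(ratio, na.rm = TRUE)
  class(out) <- c("ratio_trace", "data.frame")
  out
}
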
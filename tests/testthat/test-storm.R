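make_cluster_dets <- function(n, cx, cy, spread, n_frames,
                              frame_interval = 0.05, seed = 1) {
  withr::with_seed(seed, {
    detection_table(
      sort(sample.int(n_frames, n, replace = TRUE) - 1L),
      rnorm(n, cx, spread), rnorm(n, cy, spread),
      frame_interval = frame_interval, n_frames = n_frames
    )
  })
}

test_that("drift of a static field is estimated as ~zero", {
  dets <- make_cluster_dets(4000, 500, 500, 10, n_frames = 6000)
  tr <- estimate_drift(dets, window_size = 1000, window_step = 250)
  # COM noise: spread 10 nm over ~650 detections/window, reference
  # subtraction doubles the variance; allow ~4.5 sigma for the max
  expect_lt(max(abs(c(tr$dx, tr$dy))), 4.5 * sqrt(2) * 10 / sqrt(650))
})

test_that("injected linear drift is recovered per-frame", {
  n_frames <- 6000
  sim <- simulate_storm(storm_sim_config(
    n_frames = n_frames,
    clusters = data.frame(cx = 500, cy = 500, radius = 100,
                          n_emitters = 150),
    mean_bursts = 20, localization_sigma = 10,
    drift_model = "linear", drift_rate = c(1, -0.5), seed = 5
  ))
  tr <- estimate_drift(sim$detections, window_size = 1000,
                       window_step = 250)
  truth <- sim$truth$true_drift
  # compare up to the common reference (drift is relative)
  err_x <- (tr$dx - truth$dx) - mean(tr$dx - truth$dx)
  err_y <- (tr$dy - truth$dy) - mean(tr$dy - truth$dy)
  rmse <- sqrt(mean(err_x^2 + err_y^2))
  expect_lt(rmse, 10)
  # correcting shrinks the detection cloud of the static emitters
  corr <- apply_drift(sim$detections, tr)
  expect_lt(sd(corr$x), sd(sim$detections$x))
  expect_lt(sd(corr$y), sd(sim$detections$y))
})

test_that("a zero trace leaves detections unchanged", {
  dets <- make_cluster_dets(200, 100, 100, 5, n_frames = 100)
  tr <- data.frame(frame = 0:99, dx = 0, dy = 0)
  out <- apply_drift(dets, tr)
  expect_equal(out$x, dets$x)
  expect_equal(out$y, dets$y)
})

test_that("drift-correct after drift-estimate is a near fixed point", {
  sim <- simulate_storm(storm_sim_config(
    n_frames = 4000,
    clusters = data.frame(cx = 0, cy = 0, radius = 80, n_emitters = 150),
    mean_bursts = 15, localization_sigma = 10,
    drift_model = "linear", drift_rate = c(0.5, 0.2), seed = 6
  ))
  tr <- estimate_drift(sim$detections, window_size = 1000,
                       window_step = 250)
  corrected <- apply_drift(sim$detections, tr)
  tr2 <- estimate_drift(corrected, window_size = 1000, window_step = 250)
  expect_lt(max(abs(c(tr2$dx, tr2$dy))), 3)
})

test_that("detections merge per the 2-sigma / 15-s rule", {
  sig <- 25
  # 1 sigma apart, 5 s apart (frame interval 0.05 -> 100 frames)
  d1 <- detection_table(c(0, 100), c(0, sig), c(0, 0), 0.05)
  m1 <- merge_detections(d1, sigma = sig)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$n_detections, 2L)
  # 10 sigma apart: distinct molecules
  d2 <- detection_table(c(0, 100), c(0, 10 * sig), c(0, 0), 0.05)
  expect_equal(nrow(merge_detections(d2, sigma = sig)), 2)
})

test_that("blinking trains chain within 15 s and split beyond", {
  frames_ok <- as.integer(c(0, 280, 560, 840, 1120, 1400, 1680, 1960))
  d <- detection_table(frames_ok, rep(0, 8), rep(0, 8), 0.05)
  expect_equal(nrow(merge_detections(d)), 1) # gaps of 14 s
  frames_gap <- as.integer(c(0, 280, 560, 960, 1240))
  d2 <- detection_table(frames_gap, rep(0, 5), rep(0, 5), 0.05)
  expect_equal(nrow(merge_detections(d2)), 2) # one 20 s gap
})

test_that("merging conserves detections on simulated streams", {
  sim <- simulate_storm(storm_sim_config(
    n_frames = 2000,
    clusters = data.frame(cx = c(0, 400), cy = c(0, 0), radius = 50,
                          n_emitters = 20),
    mean_bursts = 4, localization_sigma = 10, seed = 8
  ))
  m <- merge_detections(sim$detections)
  expect_equal(sum(m$n_detections), nrow(sim$detections))
  expect_true(all(m$n_detections >= 1))
  expect_true(all(m$first_frame <= m$last_frame))
})

test_that("rendering bins coordinates with a pixel-corner origin", {
  d <- detection_table(0L, 100, 100, 0.05)
  img <- render_detections(d, pixel_size = 20, origin = c(0, 0))
  # (100, 100) nm at 20 nm pixels -> 0-based pixel (5, 5)
  expect_equal(img$counts[6, 6], 1L)
  expect_equal(sum(img$counts), 1L)
})

test_that("rendered pixel counts sum to the detection count", {
  dets <- make_cluster_dets(1500, 300, 200, 60, n_frames = 1000, seed = 3)
  img <- render_detections(dets)
  expect_equal(sum(img$counts), nrow(dets))
  expect_equal(img$pixel_size, 20)
})

test_that("an empty table cannot be rendered", {
  d <- detection_table(integer(0), numeric(0), numeric(0), 0.05)
  expect_error(render_detections(d), "empty")
})

test_that("segmentation recovers a large planted cluster quantitatively", {
  # radius large against the 20 nm pixel so quantization is benign
  r <- 300
  sim <- simulate_storm(storm_sim_config(
    n_frames = 20000,
    clusters = data.frame(cx = 0, cy = 0, radius = r, n_emitters = 2000),
    mean_bursts = 2, mean_burst_len = 5,
    localization_sigma = 5, seed = 11
  ))
  img <- render_detections(sim$detections)
  cl <- segment_nanoclusters(img, min_density = 0, min_detections = 10)
  expect_equal(nrow(cl), 1)
  expect_lt(abs(cl$area - pi * r^2) / (pi * r^2), 0.25)
  # identity: density * area = detections, exactly
  expect_equal(cl$density * cl$area, as.numeric(cl$n_detections))
})

test_that("clusters below the detection minimum are rejected", {
  d <- detection_table(0:8, rnorm(9, 0, 3), rnorm(9, 0, 3), 0.05)
  img <- render_detections(d)
  cl <- segment_nanoclusters(img, min_density = 0, min_detections = 10)
  expect_equal(nrow(cl), 0)
  cl2 <- segment_nanoclusters(img, min_density = 0, min_detections = 9)
  expect_gte(nrow(cl2), 1)
})

test_that("sparse background below the intensity threshold yields nothing", {
  set.seed(12)
  # one hot pixel (repeated detections) + scattered singletons: with a 20%
  # intensity threshold the singletons binarize away and fail min_detections
  d <- detection_table(
    0:59, c(rep(5, 40), runif(20, 100, 2000)),
    c(rep(5, 40), runif(20, 100, 2000)), 0.05
  )
  img <- render_detections(d)
  cl <- segment_nanoclusters(img, intensity_frac = 0.2, min_density = 0,
                             min_detections = 41)
  expect_equal(nrow(cl), 0)
})

test_that("segmentation is invariant to integer-pixel translation", {
  dets <- make_cluster_dets(800, 200, 200, 30, n_frames = 500, seed = 4)
  img1 <- render_detections(dets, origin = c(0, 0))
  shift <- dets
  shift$x <- shift$x + 7 * 20
  shift$y <- shift$y - 3 * 20
  img2 <- render_detections(shift, origin = c(0, -5 * 20))
  c1 <- segment_nanoclusters(img1, min_density = 0)
  c2 <- segment_nanoclusters(img2, min_density = 0)
  expect_equal(c1$area, c2$area)
  expect_equal(c1$n_detections, c2$n_detections)
  expect_equal(c1$density, c2$density)
})

test_that("two planted clusters report areas in the planted ratio", {
  r1 <- 150; r2 <- sqrt(2) * 150 # areas A and 2A
  sim <- simulate_storm(storm_sim_config(
    n_frames = 20000,
    clusters = data.frame(cx = c(0, 2000), cy = c(0, 0),
                          radius = c(r1, r2), n_emitters = c(80, 160)),
    mean_bursts = 40, mean_burst_len = 4, localization_sigma = 5,
    seed = 13
  ))
  img <- render_detections(sim$detections)
  cl <- segment_nanoclusters(img, min_density = 0, min_detections = 10)
  expect_equal(nrow(cl), 2)
  ratio <- max(cl$area) / min(cl$area)
  expect_lt(abs(ratio - 2) / 2, 0.15)
})

test_that("molecule counts attach to segmented clusters", {
  sim <- simulate_storm(storm_sim_config(
    n_frames = 5000,
    clusters = data.frame(cx = 0, cy = 0, radius = 100, n_emitters = 30),
    mean_bursts = 5, localization_sigma = 8, seed = 14
  ))
  mols <- merge_detections(sim$detections)
  img <- render_detections(sim$detections)
  cl <- segment_nanoclusters(img, min_density = 0, molecules = mols)
  expect_true("n_molecules" %in% names(cl))
  expect_true(all(cl$n_molecules <= nrow(mols)))
  expect_gt(sum(cl$n_molecules), 0)
})

test_that("cluster_report tags rows with metadata and passes empties", {
  empty <- segment_nanoclusters(
    render_detections(detection_table(0L, 0, 0, 0.05)),
    min_detections = 10, min_density = 0
  )
  expect_equal(nrow(cluster_report(empty)), 0)
  fake <- data.frame(cluster_id = 1:2, n_pixels = c(4L, 8L),
                     area = c(1600, 3200), n_detections = c(40L, 80L),
                     density = c(0.025, 0.025))
  rep <- cluster_report(fake, metadata = list(condition = "control",
                                              culture = 1, neuron = 2))
  expect_equal(rep$condition, rep("control", 2))
  expect_true(all(c("area", "n_detections", "density") %in% names(rep)))
})
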
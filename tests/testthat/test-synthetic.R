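test_that("zero-motion, zero-noise trajectories stay at the start", {
  cfg <- traj_sim_config(
    n_frames = 50, diffusion_coeff = 0, localization_sigma = 0,
    start = c(1, 2), seed = 1
  )
  tr <- simulate_trajectory(cfg)$trajectory
  expect_equal(nrow(tr), 50)
  expect_true(all(tr$x == 1) && all(tr$y == 2))
})

test_that("free Brownian increments have variance 2*D*dt per axis", {
  D <- 0.1; tau <- 0.03
  sq <- unlist(lapply(1:200, function(s) {
    tr <- simulate_trajectory(traj_sim_config(
      n_frames = 300, diffusion_coeff = D, frame_interval = tau,
      localization_sigma = 0, seed = s
    ))$trajectory
    c(diff(tr$x)^2, diff(tr$y)^2)
  }))
  se <- sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - 2 * D * tau), 3 * se)
})

test_that("simulators are bit-identical under a fixed seed", {
  cfg <- traj_sim_config(n_frames = 100, blink_off_prob = 0.1,
                         blink_on_prob = 0.5, seed = 7)
  expect_identical(simulate_trajectory(cfg), simulate_trajectory(cfg))
  scfg <- storm_sim_config(
    n_frames = 500, clusters = data.frame(cx = 0, cy = 0, radius = 50,
                                          n_emitters = 10),
    drift_model = "random_walk", drift_sd = 0.5, seed = 3
  )
  expect_identical(simulate_storm(scfg), simulate_storm(scfg))
  expect_identical(
    simulate_widefield(background_level = 7, noise_sigma = 2, seed = 5,
                       shape = c(32, 32)),
    simulate_widefield(background_level = 7, noise_sigma = 2, seed = 5,
                       shape = c(32, 32))
  )
})

test_that("blinking drops frames and records them as gaps", {
  cfg <- traj_sim_config(n_frames = 400, blink_off_prob = 0.2,
                         blink_on_prob = 0.5, seed = 11)
  sim <- simulate_trajectory(cfg)
  tr <- sim$trajectory
  expect_lt(nrow(tr), 400)
  expect_identical(tr$frame, which(sim$truth$visible[seq_len(400)])[
    seq_len(nrow(tr))] - 1L)
  expect_true(length(setdiff(0:(max(tr$frame)), tr$frame)) > 0)
})

test_that("OU confinement reaches the analytic MSD plateau", {
  r <- 0.2 # um; stationary per-axis sd r/2, 2D MSD plateau 4*(r/2)^2
  trs <- lapply(1:300, function(s) {
    simulate_trajectory(traj_sim_config(
      n_frames = 200, diffusion_coeff = 0.2, motion_model = "confined_ou",
      confinement_radius = r, localization_sigma = 0, seed = s
    ))$trajectory
  })
  msd_at <- function(lag) {
    mean(vapply(trs, function(t) {
      m <- compute_msd(t, max_lag = lag)
      m$msd[m$lag == lag]
    }, numeric(1)))
  }
  plateau <- 4 * (r / 2)^2
  late <- msd_at(150)
  expect_lt(abs(late - plateau) / plateau, 0.15)
  # ensemble curve grows towards the plateau and stays bounded
  expect_lt(msd_at(2), late)
  expect_lt(late, plateau * 1.3)
})

test_that("reflected-disc confinement never leaves the disc", {
  r <- 0.15
  tr <- simulate_trajectory(traj_sim_config(
    n_frames = 500, diffusion_coeff = 0.5, motion_model = "confined_disc",
    confinement_radius = r, localization_sigma = 0, start = c(0, 0),
    seed = 2
  ))$trajectory
  expect_true(all(tr$x^2 + tr$y^2 <= r^2 + 1e-12))
})

test_that("confined models demand a confinement radius", {
  expect_error(traj_sim_config(motion_model = "confined_ou"),
               "confinement_radius")
})

test_that("a scene without overrides reduces to independent trajectories", {
  cfgs <- lapply(1:3, function(k) {
    traj_sim_config(n_frames = 60, seed = 20 + k)
  })
  scene <- simulate_scene(scene_config(seed = 1), cfgs)
  solo <- lapply(cfgs, function(cc) simulate_trajectory(cc)$trajectory)
  for (k in 1:3) {
    expect_equal(scene$trajectories[[k]]$x, solo[[k]]$x)
    expect_equal(scene$trajectories[[k]]$y, solo[[k]]$y)
  }
})

test_that("a confined override pins a trajectory to its disc", {
  r <- 0.3
  discs <- data.frame(class = "inhibitory", cx = 3, cy = 3, r = r)
  sc <- scene_config(
    image_shape = c(64, 64), discs = discs,
    overrides = list(inhibitory = list(
      motion_model = "confined_ou", confinement_radius = r / 2
    )),
    seed = 5
  )
  tc <- traj_sim_config(n_frames = 1200, diffusion_coeff = 0.1,
                        start = c(3, 3), localization_sigma = 0.02,
                        seed = 6)
  out <- simulate_scene(sc, list(tc))
  tp <- out$truth[[1]]$true_positions
  d <- sqrt((tp$x - 3)^2 + (tp$y - 3)^2)
  expect_true(all(d < 3 * r))
  expect_true(is.matrix(out$masks$inhibitory))
})

test_that("scene masks of different classes must not overlap", {
  discs <- data.frame(
    class = c("inhibitory", "excitatory"),
    cx = c(2, 2.05), cy = c(2, 2), r = c(0.5, 0.5)
  )
  expect_error(scene_config(discs = discs), "overlap")
})

test_that("storm: zero jitter and no drift puts detections on emitters", {
  cfg <- storm_sim_config(
    n_frames = 300, clusters = data.frame(cx = 100, cy = 200, radius = 1,
                                          n_emitters = 1),
    localization_sigma = 0, mean_bursts = 2, seed = 9
  )
  sim <- simulate_storm(cfg)
  d <- sim$detections
  expect_gt(nrow(d), 0)
  expect_equal(length(unique(d$x)), 1)
  expect_equal(length(unique(d$y)), 1)
  # alignment: every detection maps to exactly one true emitter
  expect_true(all(d$emitter %in% sim$truth$emitters$id))
})

test_that("storm: linear drift displaces a static emitter by rate*frame", {
  cfg <- storm_sim_config(
    n_frames = 100, clusters = data.frame(cx = 0, cy = 0, radius = 1e-9,
                                          n_emitters = 1),
    localization_sigma = 0, drift_model = "linear", drift_rate = c(2, -1),
    mean_bursts = 5, seed = 4
  )
  sim <- simulate_storm(cfg)
  d <- sim$detections
  em <- sim$truth$emitters
  expect_equal(d$x, em$x[d$emitter] + 2 * d$frame, tolerance = 1e-12)
  expect_equal(d$y, em$y[d$emitter] - 1 * d$frame, tolerance = 1e-12)
})

test_that("widefield: no puncta and no noise gives a constant image", {
  img <- simulate_widefield(background_level = 123, shape = c(40, 40))$image
  expect_true(all(img == 123L))
})

test_that("widefield: puncta outside the image are rejected", {
  expect_error(
    simulate_widefield(
      puncta = data.frame(x = 100, y = 10, sigma = 2, amplitude = 50),
      shape = c(32, 32)
    ),
    "inside"
  )
})
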
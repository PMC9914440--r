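test_that("MSD matches hand evaluation on a 3-point track", {
  tr <- trajectory(0:2, c(0, 1, 1), c(0, 0, 1), frame_interval = 1)
  m <- compute_msd(tr)
  # lag 1: ((1)^2 + (0+1)^2 at second pair)/2 = (1 + 1)/2 = 1.0
  # lag 2: (1^2 + 1^2)/1 = 2.0
  expect_equal(m$msd, c(1.0, 2.0))
  expect_equal(m$lag_time, c(1, 2))
  expect_equal(m$n_pairs, c(2L, 1L))
})

test_that("a static track has zero MSD at every lag", {
  tr <- trajectory(0:9, rep(2, 10), rep(3, 10))
  expect_true(all(compute_msd(tr)$msd == 0))
})

test_that("vectorized MSD equals the double-loop oracle, with gaps", {
  set.seed(10)
  for (r in 1:30) {
    tr <- random_traj(sample(5:120, 1), gap_frac = sample(c(0, 0.2), 1))
    a <- compute_msd(tr)
    b <- msd_oracle(tr)
    expect_equal(a$msd, b$msd, tolerance = 1e-12)
    expect_identical(a$n_pairs, as.integer(b$n_pairs))
  }
})

test_that("pairs spanning gap frames are skipped with a reduced divisor", {
  # frames 0,1,3: lag-1 has one valid pair, lag-2 one, lag-3 one
  tr <- trajectory(c(0, 1, 3), c(0, 1, 5), c(0, 0, 0), frame_interval = 1)
  m <- compute_msd(tr)
  expect_equal(m$lag, c(1, 2, 3))
  expect_equal(m$n_pairs, c(1L, 1L, 1L))
  expect_equal(m$msd, c(1, 16, 25))
})

test_that("diffusion fit is exact on exact lines", {
  tau <- 0.03
  m <- structure(
    data.frame(lag = 1:4, lag_time = tau * (1:4),
               msd = 4 * 0.1 * tau * (1:4), n_pairs = 100L),
    class = c("msd_curve", "data.frame"), frame_interval = tau
  )
  f <- fit_diffusion(m)
  expect_equal(f$D, 0.1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_false(f$nonpositive_D)

  m$msd <- rep(0.05, 4) # static: slope 0, intercept = the value
  f2 <- fit_diffusion(m)
  expect_equal(f2$D, 0)
  expect_equal(f2$intercept, 0.05)
})

test_that("fits are unavailable when fewer than four lags exist", {
  tr <- trajectory(0:2, c(0, 1, 2), c(0, 0, 0))
  f <- fit_diffusion(compute_msd(tr))
  expect_false(f$valid)
  expect_true(is.na(f$D))
})

test_that("explored area maps the default lags to indices 14 and 15", {
  tr <- random_traj(100, tau = 0.03)
  m <- compute_msd(tr)
  ea <- explored_area(m)
  expect_equal(unname(ea["0.42"]), m$msd[m$lag == 14])
  expect_equal(unname(ea["0.45"]), m$msd[m$lag == 15])
  expect_error(explored_area(m, lags = 0.431), "integer multiple")
  expect_warning(explored_area(m, lags = 30), "omitted")
})

test_that("free-diffusion ensemble EA matches 4*D*t + 4*sigma^2", {
  D <- 0.1; sig <- 0.025; tau <- 0.03
  ea <- vapply(1:300, function(s) {
    tr <- simulate_trajectory(traj_sim_config(
      n_frames = 120, diffusion_coeff = D, localization_sigma = sig,
      frame_interval = tau, seed = 100 + s
    ))$trajectory
    unname(explored_area(compute_msd(tr, max_lag = 15), 0.42))
  }, numeric(1))
  expected <- 4 * D * 0.42 + 4 * sig^2
  se <- sd(ea) / sqrt(length(ea))
  expect_lt(abs(mean(ea) - expected), 3 * se)
})

test_that("compartment classification follows the 760 nm inclusion rule", {
  mask <- matrix(FALSE, 32, 32)
  mask[10, 10] <- TRUE # pixel (9, 9) 0-based, centre at 9*190 nm
  px <- 190
  at_px <- function(ix, iy) {
    trajectory(0:1, rep(nm_to_um(ix * px), 2), rep(nm_to_um(iy * px), 2))
  }
  lab <- function(t) {
    classify_trajectory(t, list(inhibitory = mask))[["synaptic"]]
  }
  expect_equal(lab(at_px(9, 9)), "inhibitory_synaptic")   # on the mask
  expect_equal(lab(at_px(12, 9)), "inhibitory_synaptic")  # 3 px = 570 nm
  expect_equal(lab(at_px(14, 9)), "extrasynaptic")        # 5 px = 950 nm
})

test_that("two-marker classification picks the nearer marker, tie void", {
  m1 <- matrix(FALSE, 32, 32); m1[5, 16] <- TRUE
  m2 <- matrix(FALSE, 32, 32); m2[12, 16] <- TRUE
  tr <- trajectory(0:1, rep(nm_to_um(7 * 190), 2), rep(nm_to_um(15 * 190), 2))
  lab <- classify_trajectory(tr, list(inhibitory = m1, excitatory = m2))
  expect_equal(lab[["synaptic"]], "inhibitory_synaptic") # 2 px vs 5 px
  tr_mid <- trajectory(
    0:1, rep(nm_to_um(8.5 * 190), 2), rep(nm_to_um(15 * 190), 2)
  )
  # rounds to pixel 8 or 9: equidistant only at an exact tie; construct one
  m3 <- matrix(FALSE, 32, 32); m3[5, 16] <- TRUE
  m4 <- matrix(FALSE, 32, 32); m4[11, 16] <- TRUE
  tie <- trajectory(0:1, rep(nm_to_um(7 * 190), 2), rep(nm_to_um(15 * 190), 2))
  lab2 <- classify_trajectory(tie, list(inhibitory = m3, excitatory = m4))
  expect_equal(lab2[["synaptic"]], "unclassified")
})

test_that("endocytic masks yield intra/extra EZ labels", {
  mask <- matrix(FALSE, 32, 32); mask[16, 16] <- TRUE
  near <- trajectory(0:1, rep(nm_to_um(15 * 190), 2),
                     rep(nm_to_um(15 * 190), 2))
  far <- trajectory(0:1, rep(nm_to_um(25 * 190), 2),
                    rep(nm_to_um(15 * 190), 2))
  expect_equal(
    classify_trajectory(near, list(endocytic = mask))[["endocytic"]],
    "intra_EZ"
  )
  expect_equal(
    classify_trajectory(far, list(endocytic = mask))[["endocytic"]],
    "extra_EZ"
  )
})

test_that("out-of-raster localizations raise a coordinate-frame error", {
  mask <- matrix(FALSE, 8, 8); mask[2, 2] <- TRUE
  tr <- trajectory(0:1, c(0, 100), c(0, 0)) # 100 um is far off an 8 px grid
  expect_error(classify_trajectory(tr, list(inhibitory = mask)),
               "mismatched")
})

test_that("dwell time follows the in-time / exits definition exactly", {
  tau <- 0.03
  d <- sptnano:::dwell_from_labels(
    c(rep(TRUE, 10), FALSE, rep(TRUE, 7), FALSE), tau
  )
  expect_equal(d$total_synaptic_frames, 17L)
  expect_equal(d$n_exits, 2L)
  expect_equal(d$dwell_time, 17 * tau / 2) # 8.5 frames = 0.255 s
  expect_false(d$censored)
  expect_false(d$discarded)

  short <- sptnano:::dwell_from_labels(c(TRUE, TRUE, TRUE, FALSE), tau)
  expect_equal(short$dwell_time, 3 * tau)
  expect_true(short$discarded) # < 5 frames

  all_in <- sptnano:::dwell_from_labels(rep(TRUE, 20), tau)
  expect_true(all_in$censored)
  expect_equal(all_in$dwell_time, 20 * tau)

  never <- sptnano:::dwell_from_labels(rep(FALSE, 20), tau)
  expect_equal(never$total_synaptic_frames, 0L)
  expect_false(never$discarded)
})

test_that("dwell * exits equals total in-time for non-censored tracks", {
  set.seed(20)
  for (r in 1:50) {
    lab <- runif(sample(10:100, 1)) < 0.4
    d <- sptnano:::dwell_from_labels(lab, 0.03)
    if (!d$censored && d$total_synaptic_frames > 0) {
      expect_equal(d$dwell_time * d$n_exits,
                   d$total_synaptic_frames * 0.03)
    }
  }
})

test_that("dwell_time measures residence against a mask raster", {
  mask <- matrix(FALSE, 32, 32); mask[10, 10] <- TRUE
  # path: 3 frames at the mask, 2 far away, 4 at the mask again
  xs <- nm_to_um(190 * c(9, 9, 9, 20, 20, 9, 9, 9, 9))
  tr <- trajectory(0:8, xs, rep(nm_to_um(190 * 9), 9))
  d <- dwell_time(tr, mask)
  expect_equal(d$total_synaptic_frames, 7L)
  expect_equal(d$n_exits, 1L)
  expect_equal(d$dwell_time, 7 * 0.03)
})

test_that("summarize_population reduces to the single trajectory it sees", {
  tr <- simulate_trajectory(traj_sim_config(n_frames = 100, seed = 9))
  pop <- summarize_population(list(tr$trajectory))
  f <- fit_diffusion(compute_msd(tr$trajectory, max_lag = 30))
  expect_equal(pop$summary$median_D, f$D)
  expect_equal(pop$summary$n_qds, 1)
  expect_equal(pop$summary$n_ea_values, 2) # one QD x two lags
})

test_that("EA accounting multiplies QDs by configured lags", {
  trs <- lapply(1:5, function(s) {
    simulate_trajectory(traj_sim_config(n_frames = 100,
                                        seed = 40 + s))$trajectory
  })
  pop <- summarize_population(trs, ea_lags = c(0.42, 0.45))
  expect_equal(pop$summary$n_ea_values, 5 * 2)
  pop3 <- summarize_population(trs, ea_lags = c(0.3, 0.42, 0.45))
  expect_equal(pop3$summary$n_ea_values, 5 * 3)
})

test_that("populations with different D separate in the summary", {
  fast <- lapply(1:80, function(s) {
    simulate_trajectory(traj_sim_config(
      n_frames = 150, diffusion_coeff = 0.1, seed = 200 + s
    ))$trajectory
  })
  slow <- lapply(1:80, function(s) {
    simulate_trajectory(traj_sim_config(
      n_frames = 150, diffusion_coeff = 0.01, seed = 400 + s
    ))$trajectory
  })
  pop <- summarize_population(
    c(fast, slow),
    condition = rep(c("fast", "slow"), each = 80)
  )
  md <- setNames(pop$summary$median_D, pop$summary$condition)
  expect_gt(md["fast"], md["slow"])
  tt <- choose_and_test(
    pop$per_trajectory$D[pop$per_trajectory$condition == "fast"],
    pop$per_trajectory$D[pop$per_trajectory$condition == "slow"],
    method = "mw"
  )
  expect_lt(tt$p_value, 0.001)
})
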
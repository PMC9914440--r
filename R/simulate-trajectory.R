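#' Configuration for a simulated quantum-dot trajectory
#'
#' Defaults reproduce the acquisition this package targets: 1200 frames at a
#' 30 ms frame interval with ~25 nm localization accuracy. Motion models:
#' `free_brownian` (per-axis Gaussian increments of variance `2 D dt`),
#' `confined_disc` (Brownian steps reflected at a disc boundary of radius
#' `confinement_radius`), and `confined_ou` (mean-reverting Ornstein-Uhlenbeck
#' pull towards the disc centre, calibrated so the stationary per-axis
#' standard deviation equals `confinement_radius / 2`; its mean-squared
#' displacement plateau is analytic, which makes it the testable default for
#' confined motion).
#'
#' Blinking is a 2-state Markov chain on visibility: a visible quantum dot
#' turns dark with probability `blink_off_prob` per frame and a dark one
#' re-appears with probability `blink_on_prob`. Dark frames are dropped from
#' the emitted trajectory (they become gaps); the defaults disable blinking
#' since the blinking statistics of the dyes are a free parameter, not a
#' fitted value.
#'
#' @param n_frames number of acquisition frames (>= 2).
#' @param frame_interval frame interval in seconds.
#' @param diffusion_coeff diffusion coefficient D in um^2/s (>= 0).
#' @param motion_model one of `"free_brownian"`, `"confined_disc"`,
#'   `"confined_ou"`.
#' @param confinement_radius confinement radius in um (required for the
#'   confined models).
#' @param start numeric length-2 start position in um.
#' @param localization_sigma per-frame localization noise (std, um); the
#'   default 0.025 um matches the ~20-30 nm pointing accuracy of quantum
#'   dots.
#' @param blink_on_prob,blink_off_prob per-frame Markov blinking
#'   probabilities in \[0, 1\].
#' @param seed optional integer seed; identical config + seed gives
#'   bit-identical output.
#' @return a list of class `traj_sim_config`.
#' @export
traj_sim_config <- function(n_frames = 1200L,
                            frame_interval = 0.030,
                            diffusion_coeff = 0.1,
                            motion_model = c(
                              "free_brownian", "confined_ou", "confined_disc"
                            ),
                            confinement_radius = NULL,
                            start = c(0, 0),
                            localization_sigma = 0.025,
                            blink_on_prob = 1,
                            blink_off_prob = 0,
                            seed = NULL) {
  motion_model <- match.arg(motion_model)
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (diffusion_coeff < 0) stop("diffusion_coeff must be >= 0")
  if (localization_sigma < 0) stop("localization_sigma must be >= 0")
  for (p in c(blink_on_prob, blink_off_prob)) {
    if (p < 0 || p > 1) stop("blink probabilities must be in [0, 1]")
  }
  if (motion_model != "free_brownian" &&
      (is.null(confinement_radius) || confinement_radius <= 0)) {
    stop("confined models require a positive confinement_radius")
  }
  structure(
    list(
      n_frames = as.integer(n_frames), frame_interval = frame_interval,
      diffusion_coeff = diffusion_coeff, motion_model = motion_model,
      confinement_radius = confinement_radius, start = start,
      localization_sigma = localization_sigma,
      blink_on_prob = blink_on_prob, blink_off_prob = blink_off_prob,
      seed = seed
    ),
    class = "traj_sim_config"
  )
}

# One motion step from position p (length 2), returning the new true position.
# OU uses the exact discretization x' = c + (x - c) e^{-theta dt} + N(0, s2),
# s2 = (D/theta) (1 - e^{-2 theta dt}), theta = D / (r/2)^2 so that the
# stationary per-axis variance is (r/2)^2.
.step_motion <- function(p, model, D, dt, radius, center) {
  if (D <= 0) return(p)
  if (model == "free_brownian") {
    return(p + rnorm(2, 0, sqrt(2 * D * dt)))
  }
  if (model == "confined_ou") {
    theta <- D / (radius / 2)^2
    decay <- exp(-theta * dt)
    s <- sqrt((D / theta) * (1 - decay^2))
    return(center + (p - center) * decay + rnorm(2, 0, s))
  }
  # confined_disc: free step, then reflect radially at the boundary
  q <- p + rnorm(2, 0, sqrt(2 * D * dt))
  d <- sqrt(sum((q - center)^2))
  if (d > radius && d > 0) {
    q <- center + (q - center) * (2 * radius - d) / d
    # a huge overshoot could reflect past the centre; clamp inside
    d2 <- sqrt(sum((q - center)^2))
    if (d2 > radius) q <- center + (q - center) * radius / d2
  }
  q
}

#' Simulate a single quantum-dot trajectory
#'
#' Runs the motion model of [traj_sim_config()] for `n_frames` frames, applies
#' independent Gaussian localization noise per frame, then drops blinked-off
#' frames. Returns both the observed trajectory and the ground truth (ideal
#' positions for every frame, visibility, and noise-free observed positions)
#' for recovery tests.
#'
#' @param cfg a [traj_sim_config()].
#' @return list with elements `trajectory` (an [trajectory()] of the visible,
#'   noise-corrupted localizations) and `truth` (list: `true_positions`
#'   data.frame over all frames, `visible` logical vector, `config`).
#' @export
simulate_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "traj_sim_config"))
  .local_seed(cfg$seed)
  n <- cfg$n_frames
  dt <- cfg$frame_interval
  D <- cfg$diffusion_coeff
  center <- cfg$start
  pos <- matrix(0, n, 2)
  pos[1, ] <- cfg$start
  if (D <= 0) {
    pos[, 1] <- cfg$start[1]
    pos[, 2] <- cfg$start[2]
  } else if (cfg$motion_model == "free_brownian") {
    s <- sqrt(2 * D * dt)
    pos[, 1] <- cfg$start[1] + c(0, cumsum(rnorm(n - 1L, 0, s)))
    pos[, 2] <- cfg$start[2] + c(0, cumsum(rnorm(n - 1L, 0, s)))
  } else if (cfg$motion_model == "confined_ou") {
    # exact AR(1) discretization of the mean-reverting process
    theta <- D / (cfg$confinement_radius / 2)^2
    a <- exp(-theta * dt)
    s <- sqrt((D / theta) * (1 - a^2))
    for (ax in 1:2) {
      dev <- stats::filter(rnorm(n - 1L, 0, s), a, "recursive", init = 0)
      pos[, ax] <- center[ax] + c(0, as.numeric(dev))
    }
  } else {
    for (i in seq_len(n - 1L)) {
      pos[i + 1L, ] <- .step_motion(
        pos[i, ], cfg$motion_model, D, dt, cfg$confinement_radius, center
      )
    }
  }
  # blinking: 2-state Markov chain on visibility, starting visible
  visible <- logical(n)
  visible[1] <- TRUE
  if (cfg$blink_off_prob == 0 && cfg$blink_on_prob >= 1) {
    visible[] <- TRUE
  } else {
    u <- runif(n - 1L)
    for (i in seq_len(n - 1L)) {
      visible[i + 1L] <- if (visible[i]) u[i] >= cfg$blink_off_prob
                         else u[i] < cfg$blink_on_prob
    }
  }
  noise <- matrix(rnorm(2L * n, 0, cfg$localization_sigma), n, 2)
  obs <- pos + noise
  keep <- which(visible)
  if (length(keep) < 2L) keep <- c(1L, 2L)  # degenerate blinking: keep a pair
  traj <- trajectory(
    frame = keep - 1L, x = obs[keep, 1], y = obs[keep, 2],
    frame_interval = dt, particle_id = 1L
  )
  truth <- list(
    true_positions = data.frame(
      frame = seq_len(n) - 1L, x = pos[, 1], y = pos[, 2]
    ),
    visible = visible,
    config = cfg
  )
  list(trajectory = traj, truth = truth)
}

#' Scene configuration: camera grid, compartment masks, local overrides
#'
#' Describes an imaged field on the camera grid (default 190 nm pixels, the
#' camera pixel implied by the 4 px = 760 nm synaptic inclusion distance) with
#' disc-shaped compartments per marker class (`inhibitory`, `excitatory`,
#' `endocytic`). Disc geometry is in micrometres in image coordinates; pixel
#' (i, j) (0-based) is centred at (i, j) * pixel_size. Per-class overrides
#' switch a trajectory's local motion parameters whenever its true position
#' lies inside a disc of that class.
#'
#' @param image_shape integer length-2, image size in pixels.
#' @param pixel_size camera pixel size in nanometres (default 190).
#' @param discs `data.frame` with columns `class` (one of the marker classes),
#'   `cx`, `cy`, `r` (um). Discs of different classes must not overlap once
#'   rasterized, and centres must fall inside the image.
#' @param overrides named list (by class) of lists with any of
#'   `diffusion_coeff`, `motion_model`, `confinement_radius`; applied while a
#'   particle is inside a disc of that class.
#' @param seed optional integer seed for [simulate_scene()].
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(64L, 64L),
                         pixel_size = 190,
                         discs = NULL,
                         overrides = list(),
                         seed = NULL) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  classes <- c("inhibitory", "excitatory", "endocytic")
  if (!is.null(discs)) {
    stopifnot(all(c("class", "cx", "cy", "r") %in% names(discs)))
    if (!all(discs$class %in% classes)) {
      stop("disc classes must be one of: ", paste(classes, collapse = ", "))
    }
    lim <- nm_to_um((image_shape - 1L) * pixel_size)
    inside <- discs$cx >= 0 & discs$cx <= lim[1] &
      discs$cy >= 0 & discs$cy <= lim[2]
    if (!all(inside)) stop("disc centers must lie inside the image")
  }
  if (length(overrides) && !all(names(overrides) %in% classes)) {
    stop("override names must be marker classes")
  }
  cfg <- structure(
    list(
      image_shape = as.integer(image_shape), pixel_size = pixel_size,
      discs = discs, overrides = overrides, seed = seed
    ),
    class = "scene_config"
  )
  # rasterize now so overlapping classes fail fast
  cfg$masks <- rasterize_scene_masks(cfg)
  cfg
}

#' Rasterize the compartment discs of a scene to binary masks
#'
#' One binary matrix per marker class present, on the camera grid
#' (pixel-centre convention): a pixel belongs to the mask when its centre is
#' within a disc of that class. Errors if rasterized discs of different
#' classes overlap.
#'
#' @param cfg a [scene_config()].
#' @return named list of logical matrices (`image_shape[1]` x
#'   `image_shape[2]`), possibly empty.
#' @export
rasterize_scene_masks <- function(cfg) {
  if (is.null(cfg$discs) || nrow(cfg$discs) == 0L) return(list())
  nx <- cfg$image_shape[1]
  ny <- cfg$image_shape[2]
  px <- nm_to_um(cfg$pixel_size)
  cx <- (seq_len(nx) - 1L) * px
  cy <- (seq_len(ny) - 1L) * px
  masks <- list()
  for (cl in unique(cfg$discs$class)) {
    m <- matrix(FALSE, nx, ny)
    dd <- cfg$discs[cfg$discs$class == cl, , drop = FALSE]
    for (k in seq_len(nrow(dd))) {
      d2 <- outer((cx - dd$cx[k])^2, (cy - dd$cy[k])^2, "+")
      m <- m | (d2 <= dd$r[k]^2)
    }
    masks[[cl]] <- m
  }
  if (length(masks) > 1L) {
    tot <- Reduce(`+`, lapply(masks, function(m) m * 1L))
    if (any(tot > 1L)) stop("compartment masks of different classes overlap")
  }
  masks
}

# which override class (or NA) applies at true position p
.compartment_at <- function(p, discs, override_classes) {
  if (is.null(discs)) return(NA_character_)
  for (k in seq_len(nrow(discs))) {
    cl <- discs$class[k]
    if (!(cl %in% override_classes)) next
    if ((p[1] - discs$cx[k])^2 + (p[2] - discs$cy[k])^2 <= discs$r[k]^2) {
      return(cl)
    }
  }
  NA_character_
}

#' Simulate an imaged scene: trajectories with compartment-dependent motion
#'
#' Runs each trajectory config inside the scene; at every step the motion
#' parameters switch to the compartment override of the disc the true
#' position currently lies in (confined overrides pull towards that disc's
#' centre). Without masks/overrides this reduces exactly to independent
#' [simulate_trajectory()] calls.
#'
#' @param cfg a [scene_config()].
#' @param traj_cfgs list of [traj_sim_config()]s.
#' @return list with `trajectories` (list of [trajectory()]), `masks` (named
#'   list of logical matrices), `truth` (per-trajectory ground truth lists).
#' @export
simulate_scene <- function(cfg, traj_cfgs) {
  stopifnot(inherits(cfg, "scene_config"))
  if (inherits(traj_cfgs, "traj_sim_config")) traj_cfgs <- list(traj_cfgs)
  .local_seed(cfg$seed)
  no_override <- length(cfg$overrides) == 0L
  trajs <- vector("list", length(traj_cfgs))
  truths <- vector("list", length(traj_cfgs))
  for (t in seq_along(traj_cfgs)) {
    tc <- traj_cfgs[[t]]
    stopifnot(inherits(tc, "traj_sim_config"))
    if (no_override) {
      sim <- simulate_trajectory(tc)
      sim$trajectory <- `attr<-`(sim$trajectory, "particle_id", t)
      trajs[[t]] <- sim$trajectory
      truths[[t]] <- sim$truth
      next
    }
    .local_seed(tc$seed)
    n <- tc$n_frames
    dt <- tc$frame_interval
    pos <- matrix(0, n, 2)
    pos[1, ] <- tc$start
    comp <- character(n)
    oc <- names(cfg$overrides)
    for (i in seq_len(n - 1L)) {
      here <- .compartment_at(pos[i, ], cfg$discs, oc)
      comp[i] <- if (is.na(here)) "none" else here
      if (is.na(here)) {
        pos[i + 1L, ] <- .step_motion(
          pos[i, ], tc$motion_model, tc$diffusion_coeff, dt,
          tc$confinement_radius, tc$start
        )
      } else {
        ov <- cfg$overrides[[here]]
        model <- ov$motion_model %||% tc$motion_model
        D <- ov$diffusion_coeff %||% tc$diffusion_coeff
        # confined overrides centre on the disc the particle is in
        dd <- cfg$discs[cfg$discs$class == here, , drop = FALSE]
        inside <- (pos[i, 1] - dd$cx)^2 + (pos[i, 2] - dd$cy)^2 <= dd$r^2
        k <- which(inside)[1]
        radius <- ov$confinement_radius %||% dd$r[k]
        pos[i + 1L, ] <- .step_motion(
          pos[i, ], model, D, dt, radius, c(dd$cx[k], dd$cy[k])
        )
      }
    }
    comp[n] <- comp[n - 1L]
    obs <- pos + matrix(rnorm(2L * n, 0, tc$localization_sigma), n, 2)
    trajs[[t]] <- trajectory(
      frame = seq_len(n) - 1L, x = obs[, 1], y = obs[, 2],
      frame_interval = dt, particle_id = t
    )
    truths[[t]] <- list(
      true_positions = data.frame(
        frame = seq_len(n) - 1L, x = pos[, 1], y = pos[, 2]
      ),
      true_labels = comp,
      config = tc
    )
  }
  list(trajectories = trajs, masks = cfg$masks, truth = truths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
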
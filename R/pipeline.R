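#' Run an end-to-end analysis pipeline from a single configuration
#'
#' Orchestrates the package's stages under one config and one root seed,
#' writing stage outputs (CSV) and a JSON manifest with the parameters, the
#' seed, per-stage exclusion counts and the MD5 checksum of every written
#' file, so identical config + seed reruns are verifiably bit-identical.
#'
#' Modes:
#' \describe{
#'   \item{`spt`}{`input$trajectories` (CSV, see [write_trajectories()]) ->
#'     per-trajectory metrics and per-condition summary.}
#'   \item{`storm`}{`input$detections` (CSV) -> drift correction (optional),
#'     detection merging, rendering, nanocluster segmentation, cluster
#'     table.}
#'   \item{`widefield`}{`input$image` (TIFF) + `analysis$threshold` ->
#'     background flattening and cluster quantification.}
#'   \item{`scenario`}{two simulated SPT conditions (control/treated) ->
#'     full chain: simulate, crossing removal, metrics, summary, and a
#'     Mann-Whitney comparison of D and EA. `scenario$control` /
#'     `scenario$treated` hold [traj_sim_config()] fields plus
#'     `n_trajectories`.}
#' }
#'
#' All randomness flows from the root `seed`, split deterministically per
#' stage; any stage failure aborts with the stage name in the message.
#'
#' @param config named list or path to a YAML file ([read_run_config()]).
#'   Fields: `mode`, `input`, `analysis`, `scenario` (mode-dependent).
#' @param out_dir output directory (created if needed); NULL = no files
#'   written, results only returned.
#' @param seed root integer seed (overrides `config$seed`).
#' @return list with the stage results and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  mode <- config$mode %||% stop("pipeline: config$mode is required")
  seed <- seed %||% config$seed %||% 1L
  if (!mode %in% c("spt", "storm", "widefield", "scenario")) {
    stop("pipeline: unknown mode '", mode, "'")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message("[pipeline] ", msg)
  }
  files <- character(0)
  emit <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    invisible(p)
  }
  counts <- list()
  result <- switch(mode,
    scenario = {
      sc <- config$scenario %||%
        stop("pipeline stage 'scenario': missing config$scenario")
      ana <- config$analysis %||% list()
      ea_lags <- ana$ea_lags %||% c(0.42, 0.45)
      sim_condition <- function(spec, cond, seed_offset, y_base) {
        n_traj <- spec$n_traj %||% spec$n_trajectories %||%
          stop("pipeline stage 'simulate': n_trajectories missing for ",
               cond)
        fields <- spec[setdiff(names(spec), c("n_traj", "n_trajectories"))]
        trajs <- lapply(seq_len(n_traj), function(k) {
          # each QD imaged in its own neighbourhood: spread starts on a
          # grid so only genuinely co-localized tracks count as crossing
          extra <- list(seed = seed + seed_offset + k)
          if (is.null(fields$start)) {
            extra$start <- c(20 * (k %% 100), 20 * (k %/% 100) + y_base)
          }
          cfg <- do.call(traj_sim_config, c(fields, extra))
          simulate_trajectory(cfg)$trajectory
        })
        note("simulated %d trajectories (%s)", n_traj, cond)
        trajs
      }
      ctrl <- sim_condition(sc$control, "control", 0L, 0)
      trt <- sim_condition(sc$treated, "treated", 1000000L, 10)
      all_trajs <- c(ctrl, trt)
      for (k in seq_along(all_trajs)) {
        attr(all_trajs[[k]], "particle_id") <- k
      }
      cond <- rep(c("control", "treated"), c(length(ctrl), length(trt)))
      cross <- remove_crossing_tracks(
        all_trajs,
        crossing_radius = ana$crossing_radius %||% 0.5
      )
      counts$n_input_trajectories <- length(all_trajs)
      counts$n_crossing_removed <- length(cross$removed)
      kept <- cross$kept
      kept_cond <- cond[vapply(
        kept, function(t) attr(t, "particle_id"), integer(1)
      )]
      pop <- summarize_population(
        kept, condition = kept_cond, ea_lags = ea_lags,
        max_lag = ana$max_lag %||% 30L
      )
      counts$n_nonpositive_D <- pop$counts$n_nonpositive_D
      ea_col <- paste0("EA_", format(ea_lags[1]))
      d_ctrl <- pop$per_trajectory$D[pop$per_trajectory$condition ==
                                       "control"]
      d_trt <- pop$per_trajectory$D[pop$per_trajectory$condition ==
                                      "treated"]
      ea_ctrl <- pop$per_trajectory[[ea_col]][
        pop$per_trajectory$condition == "control"]
      ea_trt <- pop$per_trajectory[[ea_col]][
        pop$per_trajectory$condition == "treated"]
      test_d <- choose_and_test(d_ctrl, d_trt, method = "mw")
      test_ea <- choose_and_test(ea_ctrl, ea_trt, method = "mw")
      note("median D control %.4g treated %.4g, MW p = %.3g",
           median(d_ctrl, na.rm = TRUE), median(d_trt, na.rm = TRUE),
           test_d$p_value)
      emit(pop$per_trajectory, "per_trajectory.csv")
      emit(pop$summary, "summary.csv")
      emit(pop$msd_mean, "msd_mean.csv")
      list(population = pop, test_D = test_d, test_EA = test_ea)
    },
    spt = {
      inp <- config$input %||% list()
      if (is.null(inp$trajectories) || !file.exists(inp$trajectories)) {
        stop("pipeline stage 'read-trajectories': ",
             "missing input$trajectories file")
      }
      ana <- config$analysis %||% list()
      trajs <- read_trajectories(
        inp$trajectories,
        frame_interval = ana$frame_interval %||% 0.030
      )
      note("read %d trajectories", length(trajs))
      cross <- remove_crossing_tracks(
        trajs, crossing_radius = ana$crossing_radius %||% 0.5
      )
      counts$n_input_trajectories <- length(trajs)
      counts$n_crossing_removed <- length(cross$removed)
      usable <- Filter(function(t) nrow(t) >= 5, cross$kept)
      pop <- summarize_population(
        usable, condition = ana$condition %||% "all",
        ea_lags = ana$ea_lags %||% c(0.42, 0.45),
        max_lag = ana$max_lag %||% 30L
      )
      counts$n_nonpositive_D <- pop$counts$n_nonpositive_D
      emit(pop$per_trajectory, "per_trajectory.csv")
      emit(pop$summary, "summary.csv")
      list(population = pop)
    },
    storm = {
      inp <- config$input %||% list()
      if (is.null(inp$detections) || !file.exists(inp$detections)) {
        stop("pipeline stage 'read-detections': ",
             "missing input$detections file")
      }
      ana <- config$analysis %||% list()
      raw <- read_localizations(inp$detections)
      dets <- detection_table(
        raw$frame, raw$x, raw$y,
        frame_interval = ana$frame_interval %||% 0.050
      )
      note("read %d detections", nrow(dets))
      if (isTRUE(ana$drift_correct)) {
        trace <- estimate_drift(
          dets,
          window_size = ana$drift_window %||% 2000L,
          window_step = ana$drift_step %||% 500L
        )
        dets <- apply_drift(dets, trace)
        note("drift corrected (max |d| = %.1f nm)",
             max(abs(c(trace$dx, trace$dy))))
      }
      mols <- merge_detections(
        dets, sigma = ana$sigma %||% 25,
        time_window = ana$merge_window %||% 15
      )
      counts$n_detections <- nrow(dets)
      counts$n_molecules <- nrow(mols)
      img <- render_detections(dets, pixel_size = ana$pixel_size %||% 20)
      cl <- segment_nanoclusters(
        img,
        intensity_frac = ana$intensity_frac %||% 0.01,
        min_density = ana$min_density %||% 0.1,
        min_detections = ana$min_detections %||% 10L,
        molecules = mols
      )
      counts$n_clusters <- nrow(cl)
      rep_tab <- cluster_report(cl, metadata = ana$metadata %||% list())
      emit(mols, "molecules.csv")
      emit(rep_tab, "clusters.csv")
      list(molecules = mols, render = img, clusters = rep_tab)
    },
    widefield = {
      inp <- config$input %||% list()
      if (is.null(inp$image) || !file.exists(inp$image)) {
        stop("pipeline stage 'read-image': missing input$image file")
      }
      ana <- config$analysis %||% list()
      if (is.null(ana$threshold)) {
        stop("pipeline stage 'segment': analysis$threshold is required")
      }
      raw <- read_image_tiff(inp$image)
      flat <- flatten_background(raw, ana$kernel_size %||% 3L)
      seg <- segment_wf_clusters(
        flat, raw, roi = NULL, threshold = ana$threshold,
        pixel_size = ana$pixel_size %||% 190
      )
      counts$n_clusters <- seg$n_clusters
      emit(seg$clusters, "wf_clusters.csv")
      list(segmentation = seg)
    }
  )
  manifest <- list(
    mode = mode, seed = seed,
    parameters = config$analysis %||% list(),
    counts = counts,
    package_version = as.character(utils::packageVersion("sptnano")),
    files = if (length(files)) {
      data.frame(file = basename(files),
                 md5 = unname(tools::md5sum(files)))
    } else NULL
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  c(result, list(manifest = manifest, log = log_lines))
}
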
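## Orchestration and file I/O: fixed CSV dialects for every intermediate
## product, a YAML run configuration, an end-to-end pipeline driver and a
## schema/sanity validator. Identical configuration + seeds give
## byte-identical result CSVs.

#' Write / read a per-camera 2D track CSV
#'
#' Columns `frame, x_px, y_px`; blank cells mark frames that were not
#' digitised.
#'
#' @param track A [pixel_track()].
#' @param path CSV path.
#' @return `read_track_csv` returns a [pixel_track()].
#' @export
write_track_csv <- function(track, path) {
  df <- data.frame(frame = track$frame_index,
                   x_px = ifelse(track$valid, track$xy[, 1], NA),
                   y_px = ifelse(track$valid, track$xy[, 2], NA))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_track_csv
#' @param camera_id Camera label for the reconstructed track.
#' @export
read_track_csv <- function(path, camera_id = "cam") {
  df <- utils::read.csv(path)
  need_cols(df, c("frame", "x_px", "y_px"), path)
  pixel_track(df$frame, cbind(df$x_px, df$y_px), camera_id = camera_id)
}

#' Write / read a wand observation CSV
#'
#' One row per frame: `frame, c1_ax, c1_ay, c1_bx, c1_by, c2_ax, c2_ay,
#' c2_bx, c2_by` (pixels; blank = endpoint not visible).
#'
#' @param obs A [wand_observation()].
#' @param path CSV path.
#' @param wand_length,image_width,image_height Metadata for re-reading.
#' @export
write_wand_csv <- function(obs, path) {
  df <- data.frame(frame = obs$frame_index,
                   c1_ax = obs$cam1_a[, 1], c1_ay = obs$cam1_a[, 2],
                   c1_bx = obs$cam1_b[, 1], c1_by = obs$cam1_b[, 2],
                   c2_ax = obs$cam2_a[, 1], c2_ay = obs$cam2_a[, 2],
                   c2_bx = obs$cam2_b[, 1], c2_by = obs$cam2_b[, 2])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_wand_csv
#' @export
read_wand_csv <- function(path, wand_length = 0.24, image_width = 2560,
                          image_height = 1440) {
  df <- utils::read.csv(path)
  need_cols(df, c("frame", "c1_ax", "c1_ay", "c1_bx", "c1_by",
                  "c2_ax", "c2_ay", "c2_bx", "c2_by"), path)
  wand_observation(df$frame, cbind(df$c1_ax, df$c1_ay),
                   cbind(df$c1_bx, df$c1_by), cbind(df$c2_ax, df$c2_ay),
                   cbind(df$c2_bx, df$c2_by), wand_length = wand_length,
                   image_width = image_width, image_height = image_height)
}

#' Write / read camera calibration files
#'
#' Plain-text calibration: per camera a line of the 11 DLT coefficients
#' followed by k1, whitespace-separated.
#'
#' @param cams List of [camera_model()]s.
#' @param path File path.
#' @export
write_calibration <- function(cams, path) {
  lines <- vapply(cams, function(cm)
    paste(format(c(cm$dlt, cm$k1), digits = 17), collapse = " "),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @param image_width,image_height Sensor size to attach.
#' @export
read_calibration <- function(path, image_width = 2560, image_height = 1440) {
  lines <- readLines(path)
  lapply(seq_along(lines), function(i) {
    v <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
    if (length(v) != 12)
      stop("read_calibration: line ", i, " must hold 11 DLT coefficients + k1")
    camera_model(v[1:11], k1 = v[12], image_width = image_width,
                 image_height = image_height, id = paste0("cam", i))
  })
}

need_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
}

#' Run configuration
#'
#' Reads a YAML run configuration (`key: value` blocks for the scene,
#' cohort and smoothing settings) and fills defaults.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @param overrides Named list overriding file values.
#' @return A list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(seed = 1L, out_dir = "pipeline_out",
              scene = list(), cohort = list(n_demo_tracks = 4L),
              wand = list(n_poses = 120L, noise_sd = 0.5),
              smoothing = list(q = NULL, r = NULL))
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, file_cfg)
  }
  cfg <- utils::modifyList(cfg, overrides)
  class(cfg) <- "run_config"
  cfg
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes simulate -> calibrate -> triangulate -> smooth -> kinematics ->
#' morphometrics -> statistics on a synthetic cohort, writing every
#' intermediate CSV plus a manifest (configuration, seeds, package
#' version, per-stage record counts) into the output directory. A subset
#' of stages can be selected; later stages read the files earlier stages
#' wrote, so any contiguous subrange works.
#'
#' @param config A [run_config()] (or path to one).
#' @param stages Stages to run, in order.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "calibrate", "triangulate",
                                    "smooth", "kinematics", "morpho",
                                    "stats")) {
  if (is.character(config)) config <- run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  counts <- list()
  pathf <- function(...) file.path(out, paste0(...))
  scene <- do.call(scene_config, c(config$scene,
                                   list(pixel_noise_sd = config$wand$noise_sd)))

  if ("simulate" %in% stages) {
    cohort <- generate_cohort(cohort_config(seed = seed))
    n_demo <- min(config$cohort$n_demo_tracks, nrow(cohort$tracks))
    utils::write.csv(cohort$specimens, pathf("specimens.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$tracks, pathf("tracks_params.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$wingbeats, pathf("wingbeats.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$temperatures, pathf("temperatures.csv"),
                     row.names = FALSE)
    obs <- generate_wand_sweep(scene, n_poses = config$wand$n_poses,
                               seed = seed)
    write_wand_csv(obs, pathf("wand.csv"))
    ## render the first tracks whose wingbeats were scored, so the demo
    ## summaries carry a complete parameter set
    scored <- which(!is.na(cohort$wingbeats$n_wingbeats))
    demo_rows <- scored[seq_len(n_demo)]
    demo_ids <- cohort$tracks$trajectory_id[demo_rows]
    for (k in seq_len(n_demo)) {
      row <- cohort$tracks[demo_rows[k], ]
      pf <- path_profile("helix", speed = row$profile_speed,
                         radius = row$profile_radius,
                         pitch = row$profile_pitch,
                         duration = min(row$profile_duration, 3),
                         seed = seed + k)
      gp <- generate_flight_path(pf)
      trks <- render_pixel_tracks(gp$traj, scene, seed = seed + 1000 + k)
      write_track_csv(trks[[1]], pathf(row$trajectory_id, "_cam1.csv"))
      write_track_csv(trks[[2]], pathf(row$trajectory_id, "_cam2.csv"))
    }
    writeLines(demo_ids, pathf("demo_tracks.txt"))
    counts$simulate <- list(individuals = nrow(cohort$specimens),
                            tracks = nrow(cohort$tracks),
                            rendered = n_demo)
  }

  if ("calibrate" %in% stages) {
    f <- pathf("wand.csv")
    if (!file.exists(f)) stop("missing input for stage 'calibrate': ", f)
    obs <- read_wand_csv(f, image_width = scene$resolution[1],
                         image_height = scene$resolution[2])
    cal <- wand_calibrate(obs, vertical_ref = render_vertical_ref(scene))
    write_calibration(cal$cameras, pathf("calibration.txt"))
    counts$calibrate <- list(poses = length(cal$wand_lengths),
                             mean_wand_m = cal$mean_length,
                             sd_wand_m = cal$sd_length)
  }

  demo_ids <- if (file.exists(pathf("demo_tracks.txt")))
    readLines(pathf("demo_tracks.txt")) else character(0)

  if ("triangulate" %in% stages) {
    calf <- pathf("calibration.txt")
    if (!file.exists(calf)) stop("missing input for stage 'triangulate': ", calf)
    cams <- read_calibration(calf, scene$resolution[1], scene$resolution[2])
    for (id in demo_ids) {
      t1 <- read_track_csv(pathf(id, "_cam1.csv"), "cam1")
      t2 <- read_track_csv(pathf(id, "_cam2.csv"), "cam2")
      tr <- triangulate(t1, t2, cams[[1]], cams[[2]], dt = 1 / scene$fps)
      utils::write.csv(data.frame(frame = tr$frame_index,
                                  x = tr$xyz[, 1], y = tr$xyz[, 2],
                                  z = tr$xyz[, 3], valid = tr$valid),
                       pathf(id, "_xyz.csv"), row.names = FALSE, na = "")
    }
    counts$triangulate <- list(tracks = length(demo_ids))
  }

  if ("smooth" %in% stages) {
    for (id in demo_ids) {
      f <- pathf(id, "_xyz.csv")
      if (!file.exists(f)) stop("missing input for stage 'smooth': ", f)
      df <- utils::read.csv(f)
      need_cols(df, c("frame", "x", "y", "z", "valid"), f)
      tr <- trajectory3d(df$frame, cbind(df$x, df$y, df$z),
                         valid = df$valid, dt = 1 / scene$fps)
      sm <- kalman_smooth(tr, q = config$smoothing$q, r = config$smoothing$r)
      utils::write.csv(as.data.frame(sm), pathf(id, "_smoothed.csv"),
                       row.names = FALSE)
    }
    counts$smooth <- list(tracks = length(demo_ids))
  }

  if ("kinematics" %in% stages) {
    wb <- utils::read.csv(pathf("wingbeats.csv"))
    rows <- list()
    for (id in demo_ids) {
      f <- pathf(id, "_smoothed.csv")
      if (!file.exists(f)) stop("missing input for stage 'kinematics': ", f)
      df <- utils::read.csv(f)
      st <- structure(list(dt = 1 / scene$fps, frame_index = df$frame,
                           position = as.matrix(df[, c("x", "y", "z")]),
                           velocity = as.matrix(df[, c("vx", "vy", "vz")]),
                           acceleration = as.matrix(df[, c("ax", "ay", "az")]),
                           estimated = df$estimated),
                      class = "smoothed_states")
      wrow <- wb[wb$trajectory_id == id, ]
      rec <- if (nrow(wrow) == 1)
        wingbeat_record(id, wrow$n_wingbeats, wrow$duration_s) else NULL
      rows[[id]] <- summarize_flight(st, rec, trajectory_id = id)
    }
    fs <- do.call(rbind, rows)
    utils::write.csv(fs, pathf("flight_summaries.csv"), row.names = FALSE)
    counts$kinematics <- list(summaries = nrow(fs))
  }

  if ("morpho" %in% stages) {
    spec_f <- pathf("specimens.csv")
    if (!file.exists(spec_f)) stop("missing input for stage 'morpho': ", spec_f)
    specimens <- utils::read.csv(spec_f)
    morpho <- cohort_morphology(specimens, seed = seed)
    utils::write.csv(morpho, pathf("morphology.csv"), row.names = FALSE)
    counts$morpho <- list(specimens = nrow(morpho))
  }

  if ("stats" %in% stages) {
    for (f in c("morphology.csv", "tracks_params.csv", "temperatures.csv"))
      if (!file.exists(pathf(f))) stop("missing input for stage 'stats': ",
                                       pathf(f))
    morpho <- utils::read.csv(pathf("morphology.csv"))
    tracks <- utils::read.csv(pathf("tracks_params.csv"))
    temps <- utils::read.csv(pathf("temperatures.csv"))
    pc <- pairwise_correlations(morpho)
    utils::write.csv(pc$pairs, pathf("stats_correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(anova_morphology(morpho), pathf("stats_anova.csv"),
                     row.names = FALSE)
    fit <- fit_flight_lmm("mean_velocity", tracks)
    mm <- marginal_means(fit, "form")
    utils::write.csv(mm$means, pathf("stats_emmeans_velocity.csv"),
                     row.names = FALSE)
    joined <- merge(tracks, morpho[, c("specimen_id", MORPHO_VARS)],
                    by.x = "individual_id", by.y = "specimen_id")
    eff <- morphology_effects("mean_velocity", joined)
    utils::write.csv(eff, pathf("stats_morphology_effects.csv"),
                     row.names = FALSE)
    tracks2 <- merge(tracks, temps, by = "day", sort = FALSE)
    utils::write.csv(temperature_models(tracks2),
                     pathf("stats_temperature.csv"), row.names = FALSE)
    counts$stats <- list(correlations = nrow(pc$pairs))
  }

  manifest <- list(package_version = as.character(utils::packageVersion(
    "pierisflight")), seed = seed, stages = stages, counts = counts,
    config = unclass(config))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}

#' Validate pipeline CSV files
#'
#' Schema and sanity checks over the CSV dialects used by the pipeline:
#' required columns, monotone frame indices, pixel coordinates inside the
#' sensor, plausible speeds. Returns a report rather than raising.
#'
#' @param files Character vector of CSV paths.
#' @param resolution Sensor size for pixel checks.
#' @param max_speed Sanity bound on speeds (m/s).
#' @return A data frame report (file, check, ok, detail); zero failed rows
#'   means a valid bundle.
#' @export
validate_io <- function(files, resolution = c(2560, 1440), max_speed = 20) {
  rep_rows <- list()
  note <- function(file, check, ok, detail = "") {
    rep_rows[[length(rep_rows) + 1]] <<- data.frame(
      file = basename(file), check = check, ok = ok, detail = detail)
  }
  for (f in files) {
    if (!file.exists(f)) { note(f, "exists", FALSE, "missing file"); next }
    df <- tryCatch(utils::read.csv(f), error = function(e) NULL)
    if (is.null(df)) { note(f, "parse", FALSE, "unreadable CSV"); next }
    note(f, "parse", TRUE)
    if ("frame" %in% names(df)) {
      mono <- !is.unsorted(df$frame, strictly = TRUE)
      note(f, "frame_monotone", mono,
           if (!mono) "non-monotone frame index" else "")
    }
    px <- intersect(names(df), c("x_px", "c1_ax", "c1_bx", "c2_ax", "c2_bx"))
    for (cn in px) {
      v <- df[[cn]][is.finite(df[[cn]])]
      ok <- length(v) == 0 || (min(v) >= 0 && max(v) < resolution[1])
      note(f, paste0("pixel_range_", cn), ok,
           if (!ok) sprintf("%s outside [0, %d)", cn, resolution[1]) else "")
    }
    py <- intersect(names(df), c("y_px", "c1_ay", "c1_by", "c2_ay", "c2_by"))
    for (cn in py) {
      v <- df[[cn]][is.finite(df[[cn]])]
      ok <- length(v) == 0 || (min(v) >= 0 && max(v) < resolution[2])
      note(f, paste0("pixel_range_", cn), ok,
           if (!ok) sprintf("%s outside [0, %d)", cn, resolution[2]) else "")
    }
    if (all(c("vx", "vy", "vz") %in% names(df))) {
      sp <- sqrt(df$vx^2 + df$vy^2 + df$vz^2)
      ok <- all(sp < max_speed, na.rm = TRUE)
      note(f, "speed_sanity", ok,
           if (!ok) sprintf("speed above %g m/s", max_speed) else "")
    }
    if ("mean_velocity" %in% names(df)) {
      ok <- all(df$mean_velocity < max_speed, na.rm = TRUE)
      note(f, "speed_sanity", ok,
           if (!ok) sprintf("mean_velocity above %g m/s", max_speed) else "")
    }
  }
  do.call(rbind, rep_rows)
}
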
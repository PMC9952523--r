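default_config_values <- function() {
  list(
    fps_xy = 30, fps_z = 10,
    px_per_mm = 0.62, origin_u = 0, origin_v = 300,
    camera_height = 2390,
    d_min = 5, n_min = 3, max_pause = 0.5,
    conf_min = 0.6, max_gap = 5,
    moving_only = FALSE,
    alpha = 0.05,
    sigma = 2, low = 0.1, high = 0.3, rho_res = 1, theta_res = 1,
    depth_window = 5, depth_px_per_mm = 0.2,
    depth_origin_u = 10, depth_origin_v = 166,
    seed = 1
  )
}

#' Load the pipeline configuration
#'
#' Reads a flat YAML file of key-value settings, applies defaults for
#' absent keys, validates every value, and rejects unknown keys (typo
#' protection).  With no path, returns the defaults.  Keys cover the
#' acquisition rates (`fps_xy` 30 Hz video, `fps_z` 10 Hz depth), the
#' pixel-to-distance factor (`px_per_mm`, 0.62), the camera height
#' (`camera_height`, 2390 mm), the movement thresholds (`d_min` 5 mm,
#' `n_min` 3 frames, `max_pause` s), track cleaning (`conf_min`,
#' `max_gap`), the significance level (`alpha`), and the rectification
#' parameters (`sigma`, `low`, `high`, `rho_res`, `theta_res`).
#'
#' @param path Optional YAML file path.
#' @param ... Named overrides applied after the file.
#' @param quiet Suppress the effective-config echo to stderr.
#' @return A named list of class `pipeline_config`.
#' @export
load_config <- function(path = NULL, ..., quiet = TRUE) {
  cfg <- default_config_values()
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, list(...))
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(cfg, user)
  validate_config(cfg)
  if (!quiet) {
    message("effective config: ",
            paste(sprintf("%s=%s", names(cfg), unlist(cfg)), collapse = " "))
  }
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pos <- c("fps_xy", "fps_z", "px_per_mm", "camera_height", "rho_res",
           "depth_px_per_mm")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      stop("config key ", k, " must be > 0", call. = FALSE)
    }
  }
  if (cfg$d_min < 1) stop("config key d_min must be >= 1 mm", call. = FALSE)
  if (cfg$n_min < 1) stop("config key n_min must be >= 1 frame", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("config key alpha must be in (0, 1)", call. = FALSE)
  }
  if (cfg$conf_min < 0 || cfg$conf_min > 1) {
    stop("config key conf_min must be in [0, 1]", call. = FALSE)
  }
  if (cfg$max_gap < 0) stop("config key max_gap must be >= 0", call. = FALSE)
  if (cfg$low < 0 || cfg$low >= cfg$high) {
    stop("config keys low/high need 0 <= low < high", call. = FALSE)
  }
  if (cfg$theta_res <= 0 || cfg$theta_res > 5) {
    stop("config key theta_res must be in (0, 5]", call. = FALSE)
  }
  if (cfg$depth_window %% 2 != 1) {
    stop("config key depth_window must be odd", call. = FALSE)
  }
  invisible(cfg)
}

#' Run the full track-to-comparison pipeline
#'
#' For each bird in the metadata table: read its keypoint track, clean
#' it, convert to platform millimetres, optionally sample a depth
#' directory for the vertical series, extract the 16 locomotive-behavior
#' metrics, and finally compare all metrics across gait scores.  Birds
#' that fail (unreadable or unusable tracks) are skipped with a warning
#' so the cohort continues; the run fails only if no bird survives.
#'
#' @param metadata Data frame with columns `bird_id`, `gait_score` and
#'   `track_file` (pose CSV path); an optional `depth_dir` column names
#'   a directory of 16-bit depth TIFF frames (10 Hz, ordered by name).
#' @param cfg A `pipeline_config` from [load_config()].
#' @param out_dir Optional directory for tidy CSV outputs
#'   (`metrics.csv`, `comparison.csv`, per-bird event tables).
#' @return A `gait_pipeline` list: `metrics` (per-bird tibble),
#'   `comparison` (`gait_comparison`), `events` (per-bird bout and
#'   half-cycle tables), `skipped` (character vector of failed birds).
#' @export
run_pipeline <- function(metadata, cfg = load_config(), out_dir = NULL) {
  if (is.null(metadata) || nrow(metadata) == 0L) {
    stop("metadata is empty: nothing to process", call. = FALSE)
  }
  if (!all(c("bird_id", "gait_score", "track_file") %in% names(metadata))) {
    stop("metadata needs columns bird_id, gait_score, track_file",
         call. = FALSE)
  }
  metrics <- list(); events <- list(); skipped <- character()
  for (i in seq_len(nrow(metadata))) {
    id <- metadata$bird_id[i]
    res <- tryCatch(
      process_bird(metadata[i, ], cfg),
      error = function(e) {
        warning("bird ", id, " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(res)) {
      skipped <- c(skipped, id)
      next
    }
    metrics[[id]] <- res$metrics
    events[[id]] <- res$events
  }
  if (length(metrics) == 0L) {
    stop("all birds failed; no metrics to compare", call. = FALSE)
  }
  metric_tbl <- dplyr::left_join(
    dplyr::bind_rows(metrics),
    metadata[, c("bird_id", "gait_score")], by = "bird_id"
  )
  comparison <- compare_metrics(metric_tbl, alpha = cfg$alpha)
  out <- structure(list(metrics = metric_tbl, comparison = comparison,
                        events = events, skipped = skipped),
                   class = "gait_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(metric_tbl, file.path(out_dir, "metrics.csv"))
    readr::write_csv(tidy(comparison), file.path(out_dir, "comparison.csv"))
    ev <- dplyr::bind_rows(lapply(names(events), function(id) {
      dplyr::bind_rows(
        tibble::add_column(events[[id]]$bouts, kind = "forward_bout",
                           .before = 1L),
        tibble::add_column(events[[id]]$half_cycles, kind = "half_cycle",
                           .before = 1L)
      ) |> tibble::add_column(bird_id = id, .before = 1L)
    }))
    readr::write_csv(ev, file.path(out_dir, "events.csv"))
  }
  out
}

process_bird <- function(row, cfg) {
  track <- read_keypoint_csv(row$track_file, bird_id = row$bird_id,
                             fps = cfg$fps_xy)
  track <- clean_track(track, conf_min = cfg$conf_min,
                       max_gap = cfg$max_gap)
  planar <- pixels_to_mm(track, px_per_mm = cfg$px_per_mm,
                         origin_px = c(cfg$origin_u, cfg$origin_v))
  depth_track <- NULL
  has_depth <- "depth_dir" %in% names(row) && !is.na(row$depth_dir) &&
    nzchar(row$depth_dir)
  if (has_depth) {
    files <- sort(list.files(row$depth_dir, pattern = "\\.tiff?$",
                             full.names = TRUE))
    if (length(files) > 0L) {
      frames <- lapply(files, read_depth_raster)
      track_px <- tibble::tibble(
        t = planar$t,
        u = cfg$depth_origin_u + planar$x * cfg$depth_px_per_mm,
        v = cfg$depth_origin_v - planar$y * cfg$depth_px_per_mm
      )
      depth_track <- sample_depth(frames, track_px,
                                  window = cfg$depth_window,
                                  fps_z = cfg$fps_z)
    }
  }
  traj <- assemble_trajectory(planar, depth_track,
                              camera_height = cfg$camera_height,
                              fps_xy = cfg$fps_xy, fps_z = cfg$fps_z)
  bouts <- forward_bouts(traj, cfg$d_min, cfg$n_min)
  half_cycles <- lateral_half_cycles(traj, cfg$d_min, cfg$n_min,
                                     cfg$max_pause)
  m <- summarize_metrics(traj, bouts, half_cycles, d_min = cfg$d_min,
                         n_min = cfg$n_min, max_pause = cfg$max_pause,
                         moving_only = cfg$moving_only)
  m$bird_id <- row$bird_id
  list(metrics = m, events = list(bouts = bouts, half_cycles = half_cycles))
}

#' @export
print.gait_pipeline <- function(x, ...) {
  cat(sprintf("<gait_pipeline> %d birds summarized (%d skipped)\n",
              nrow(x$metrics), length(x$skipped)))
  print(x$comparison)
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
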
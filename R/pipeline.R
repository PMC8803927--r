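# End-to-end pipelines: reconstruct -> fluctuation removal -> background
# -> subtract -> segment -> track -> metrics -> summaries, and the
# two-channel invasion analogue. Every knob has a default; a config is a
# plain named list (or a YAML file of one) and all randomness flows from
# the single `rng_seed`.

#' Default pipeline configuration
#'
#' @return Named list of every stage parameter with its default.
#' @export
qpi_defaults <- function() {
  list(
    alpha_um3_per_pg = 0.18,
    background_bin_width = NULL,
    background_f_min = 0.25,
    background_d0_px = 20,
    background_refine = TRUE,
    threshold_fraction = 0.01,
    smooth_sigma_px = 1,
    min_area_um2 = 50,
    d_max_um = 30,
    mass_tol = 0.35,
    max_gap = 0L,
    hole_factor = 0.5,
    min_hole_area_um2 = 50,
    overlap_min = 0.3,
    min_track_len = 3,
    renormalize_red = FALSE,
    rng_seed = 1L
  )
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- qpi_defaults()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg
}

#' Run the full QPI pipeline
#'
#' Executes phase reconstruction, unwrapping, background fluctuation
#' removal, background reconstruction and subtraction, conversion to
#' dry mass, segmentation, tracking, and the growth/motility metrics,
#' then writes (optionally) CSV/JSON/TIFF outputs and a manifest.
#'
#' @param input either a list of `interferogram_set`s, a directory
#'   written by [write_qpi_scene()], or a [scene_spec()] (which is then
#'   simulated and rendered first).
#' @param config named list (or YAML path) overriding [qpi_defaults()].
#' @param out_dir optional output directory; when given, dry-mass maps,
#'   label images, a tracks CSV, a summary JSON and a manifest JSON are
#'   written there.
#' @return A `qpi_run`: list with `maps` (background-subtracted
#'   `dry_mass_map`s), `frames` (`labeled_frame`s), `tracks`,
#'   `growth_fits`, `protrusions`, `summary`, `background`, `config`.
#' @export
run_qpi_pipeline <- function(input, config = list(), out_dir = NULL) {
  cfg <- load_config(config)
  truth <- NULL
  if (inherits(input, "scene_spec")) {
    truth <- simulate_ground_truth(input)
    ifs_list <- render_interferograms(truth)
  } else if (is.character(input)) {
    if (!dir.exists(input) ||
        !file.exists(file.path(input, "step1.tif")))
      stop("input directory missing or not a QPI scene: ", input)
    ifs_list <- read_qpi_scene(input)
  } else ifs_list <- input
  if (!length(ifs_list)) stop("no interferogram sets to process")

  lapse <- if (length(ifs_list) > 1)
    ifs_list[[2]]$timestamp_min - ifs_list[[1]]$timestamp_min else 1
  opd <- lapply(ifs_list, function(s) unwrap_phase(reconstruct_phase(s)))
  corr <- correct_background(opd, bin_width = cfg$background_bin_width,
                             f_min = cfg$background_f_min,
                             d0_px = cfg$background_d0_px,
                             refine = cfg$background_refine,
                             threshold_fraction = cfg$threshold_fraction,
                             min_area_um2 = cfg$min_area_um2)
  maps <- lapply(corr$stack, opd_to_dry_mass,
                 alpha_um3_per_pg = cfg$alpha_um3_per_pg)
  frames <- lapply(maps, segment_frame,
                   threshold_fraction = cfg$threshold_fraction,
                   smooth_sigma_px = cfg$smooth_sigma_px,
                   min_area_um2 = cfg$min_area_um2)
  tracks <- track_frames(frames, d_max_um = cfg$d_max_um,
                         mass_tol = cfg$mass_tol, max_gap = cfg$max_gap)
  per_track <- split_tracks(tracks)
  fits <- lapply(per_track, fit_growth)
  prot <- do.call(rbind, lapply(per_track, track_protrusions,
                                frames = frames, maps = maps,
                                lapse_interval_min = lapse))
  summary <- summarize_movie(tracks, lapse, records = prot, fits = fits)
  run <- structure(list(
    maps = maps, frames = frames, tracks = tracks,
    growth_fits = fits, protrusions = prot, summary = summary,
    background = corr$background, offsets_um = corr$offsets_um,
    lapse_interval_min = lapse, config = cfg, truth = truth
  ), class = "qpi_run")
  if (!is.null(out_dir)) write_qpi_run(run, out_dir)
  run
}

#' Growth curves of a QPI run
#'
#' Dry mass of every track against time, one line per cell or cluster.
#'
#' @param x a `qpi_run`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.qpi_run <- function(x, ...) {
  tr <- x$tracks$tracks
  ids <- unique(tr$track_id)
  graphics::plot(NA, xlim = range(tr$t_min) / 60,
                 ylim = range(tr$mass_pg),
                 xlab = "time (h)", ylab = "dry mass (pg)", ...)
  for (i in seq_along(ids)) {
    d <- tr[tr$track_id == ids[i], ]
    graphics::lines(d$t_min / 60, d$mass_pg, col = i)
  }
  invisible(x)
}

#' @export
print.qpi_run <- function(x, ...) {
  cat("qpi_run:", length(x$maps), "frames,",
      length(unique(x$tracks$tracks$track_id)), "tracks\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

write_qpi_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_stack_tiff(lapply(run$maps, `[[`, "values"),
                   file.path(out_dir, "dry_mass.tif"),
                   meta = list(unit = "pg/um2"))
  write_stack_tiff(lapply(run$frames, function(f) f$labels),
                   file.path(out_dir, "labels.tif"))
  write.csv(run$tracks$tracks, file.path(out_dir, "tracks.csv"),
            row.names = FALSE)
  if (!is.null(run$protrusions))
    write.csv(run$protrusions, file.path(out_dir, "protrusions.csv"),
              row.names = FALSE)
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       digits = NA, dataframe = "rows")
  jsonlite::write_json(list(
    stage_order = c("reconstruct", "unwrap", "fluctuation_removal",
                    "background", "subtract", "dry_mass", "segment",
                    "track", "metrics"),
    parameters = run$config,
    n_frames = length(run$maps),
    lapse_interval_min = run$lapse_interval_min,
    package_version = as.character(utils::packageVersion("qpitrack"))
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the two-channel invasion pipeline
#'
#' Segments and tracks the green cancer cells, detects openings in the
#' red monolayer, and scores the invading fraction as cell-hole
#' coincidence.
#'
#' @param input an `invasion_movie`, an [invasion_scene_spec()] (rendered
#'   first), or a directory written by [write_invasion_movie()].
#' @param config named list (or YAML path) overriding [qpi_defaults()].
#' @param out_dir optional output directory for CSV/JSON outputs and a
#'   manifest.
#' @param movie_id,treatment labels for the result.
#' @return An `invasion_run`: list with `result` (an `invasion_result`),
#'   `holes`, `green`, `config`.
#' @export
run_invasion_pipeline <- function(input, config = list(), out_dir = NULL,
                                  movie_id = NA, treatment = NA) {
  cfg <- load_config(config)
  if (inherits(input, "invasion_scene_spec")) input <-
      render_invasion_movie(input)
  if (is.character(input)) {
    if (!dir.exists(input) || !file.exists(file.path(input, "red.tif")))
      stop("input directory missing or not an invasion movie: ", input)
    red <- read_stack_tiff(file.path(input, "red.tif"))
    green_stack <- read_stack_tiff(file.path(input, "green.tif"))$stack
    px <- red$meta$pixel_size_um
    lapse <- red$meta$lapse_interval_min
    red <- red$stack
  } else {
    stopifnot(inherits(input, "invasion_movie"))
    red <- input$red
    green_stack <- input$green
    px <- input$spec$pixel_size_um
    lapse <- input$spec$lapse_interval_min
  }
  holes <- detect_holes(red, pixel_size_um = px,
                        hole_factor = cfg$hole_factor,
                        min_hole_area_um2 = cfg$min_hole_area_um2,
                        renormalize = cfg$renormalize_red)
  green <- segment_track_green(green_stack, pixel_size_um = px,
                               lapse_interval_min = lapse,
                               d_max_um = cfg$d_max_um,
                               max_gap = cfg$max_gap)
  result <- score_invasion(green, holes, overlap_min = cfg$overlap_min,
                           min_track_len = cfg$min_track_len,
                           movie_id = movie_id, treatment = treatment)
  run <- structure(list(result = result, holes = holes, green = green,
                        config = cfg), class = "invasion_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(result$events))
      write.csv(result$events, file.path(out_dir, "events.csv"),
                row.names = FALSE)
    jsonlite::write_json(list(
      movie_id = movie_id, treatment = treatment,
      n_cells = result$n_cells, n_invading = result$n_invading,
      fraction = result$fraction,
      parameters = cfg,
      package_version = as.character(utils::packageVersion("qpitrack"))
    ), file.path(out_dir, "invasion.json"), auto_unbox = TRUE,
      digits = NA)
  }
  run
}

#' @export
print.invasion_run <- function(x, ...) {
  print(x$result)
  invisible(x)
}
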
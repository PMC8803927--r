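# TIFF stack I/O.
#
# tiff::writeTIFF stores samples in [0, 1]; floating-point maps are
# written min-max scaled with a JSON sidecar (<file>.json) carrying the
# affine scale and offset, so values round-trip to 32-bit float
# precision.

#' Write a list of matrices as a multi-page TIFF (scaled float)
#'
#' @param stack list of numeric matrices (or 3D array).
#' @param path output .tif path; a sidecar `<path>.json` stores the
#'   scaling.
#' @param meta optional list of extra metadata stored in the sidecar.
#' @export
write_stack_tiff <- function(stack, path, meta = list()) {
  arr <- stack_array(stack)
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(arr)[3]),
                  function(t) (arr[, , t] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- c(list(offset = lo, scale = scale,
                    n_frames = dim(arr)[3]), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path .tif path (sidecar `<path>.json` must sit next to it).
#' @return List: `stack` (list of matrices), `meta` (sidecar contents).
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side_path <- paste0(path, ".json")
  meta <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE)
    else list(offset = 0, scale = 1)
  stack <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * meta$scale + meta$offset
  })
  list(stack = stack, meta = meta)
}

#' Write a rendered QPI scene to disk
#'
#' One multi-page TIFF per phase step (pages = time points), the scene
#' spec as YAML, and a JSON ground-truth sidecar (trajectories, masses,
#' per-frame offsets).
#'
#' @param truth a [simulate_ground_truth()] result.
#' @param ifs the matching [render_interferograms()] output.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_qpi_scene <- function(truth, ifs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- truth$spec
  for (k in 1:4) {
    pages <- lapply(ifs, function(s) s$frames[[k]])
    write_stack_tiff(pages, file.path(dir, sprintf("step%d.tif", k)),
                     meta = list(phase_step_rad = spec$phase_steps_rad[k],
                                 wavelength_nm = spec$wavelength_nm,
                                 pixel_size_um = spec$pixel_size_um,
                                 lapse_interval_min = spec$lapse_interval_min))
  }
  yaml::write_yaml(scene_spec_to_list(spec), file.path(dir, "scene.yaml"))
  jsonlite::write_json(list(
    trajectories = truth$trajectories,
    masses = truth$masses,
    left_field = truth$left_field,
    offsets_um = attr(ifs, "offsets_um")
  ), file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

scene_spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$cells <- lapply(out$cells, unclass)
  out
}

#' Read a QPI scene directory back as interferogram sets
#'
#' @param dir directory written by [write_qpi_scene()].
#' @return List of `interferogram_set`s.
#' @export
read_qpi_scene <- function(dir) {
  steps <- lapply(1:4, function(k)
    read_stack_tiff(file.path(dir, sprintf("step%d.tif", k))))
  meta <- steps[[1]]$meta
  nf <- length(steps[[1]]$stack)
  phase_steps <- vapply(steps, function(s) s$meta$phase_step_rad, 0)
  lapply(seq_len(nf), function(t) {
    interferogram_set(
      lapply(steps, function(s) s$stack[[t]]),
      phase_steps_rad = phase_steps,
      wavelength_nm = meta$wavelength_nm,
      timestamp_min = (t - 1) * meta$lapse_interval_min,
      pixel_size_um = meta$pixel_size_um)
  })
}

#' Write an invasion movie to disk (red and green TIFF stacks)
#'
#' @param movie an `invasion_movie`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_invasion_movie <- function(movie, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(pixel_size_um = movie$spec$pixel_size_um,
               lapse_interval_min = movie$spec$lapse_interval_min)
  write_stack_tiff(movie$red, file.path(dir, "red.tif"), meta)
  write_stack_tiff(movie$green, file.path(dir, "green.tif"), meta)
  jsonlite::write_json(movie$truth, file.path(dir, "ground_truth.json"),
                       digits = NA)
  invisible(dir)
}
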
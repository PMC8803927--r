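#' Fit exponential growth to a track's dry-mass curve
#'
#' Ordinary least squares of log(mass) on time (hours); the dry-mass
#' doubling time is Td = ln(2) / slope. A negative slope is reported as
#' shrinking with the analogous halving time; a numerically zero slope is
#' reported as non-growing (Td = Inf). Non-positive mass points cannot
#' enter the log fit and are excluded (their count is recorded).
#'
#' @param track data.frame with columns `t_min` and `mass_pg` (one track),
#'   or a single-track subset of a `cell_tracks` object.
#' @return A `growth_fit`: track_id, slope_per_h, slope_se, doubling_time_h,
#'   status ("growing", "shrinking", "non-growing"), r_squared, n_points,
#'   n_excluded; or NULL when fewer than 3 usable points remain.
#' @export
fit_growth <- function(track) {
  if (inherits(track, "cell_tracks")) track <- track$tracks
  ok <- is.finite(track$mass_pg) & track$mass_pg > 0
  n_excluded <- sum(!ok)
  d <- track[ok, ]
  if (nrow(d) < 3) return(NULL)
  t_h <- d$t_min / 60
  fit <- stats::lm(log(d$mass_pg) ~ t_h)
  slope <- unname(coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  r2 <- summary(fit)$r.squared
  eps <- 1e-12
  status <- if (abs(slope) < eps) "non-growing"
            else if (slope > 0) "growing" else "shrinking"
  td <- if (abs(slope) < eps) Inf else log(2) / slope
  structure(list(
    track_id = if (!is.null(d$track_id)) d$track_id[1] else NA_integer_,
    slope_per_h = slope, slope_se = se,
    doubling_time_h = td, status = status,
    r_squared = r2, n_points = nrow(d), n_excluded = n_excluded
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("growth_fit (track", x$track_id, "):", x$status, "\n")
  cat("  doubling time:", signif(x$doubling_time_h, 4), "h  (slope",
      signif(x$slope_per_h, 4), "+/-", signif(x$slope_se, 3),
      "per h, r^2 =", signif(x$r_squared, 4), ")\n")
  cat("  points:", x$n_points,
      if (x$n_excluded) paste0("(", x$n_excluded, " excluded)"), "\n")
  invisible(x)
}

#' Centroid speed of a track
#'
#' Step speed is the centroid displacement between consecutive frames
#' scaled to micrometres per hour (a 5-min displacement is multiplied by
#' 12). Steps across tracking gaps (non-consecutive frame indices) are
#' excluded from the step set.
#'
#' @param track single-track data.frame (columns frame, x_um, y_um).
#' @param lapse_interval_min lapse interval in minutes.
#' @return List: `step_speeds_um_per_h`, `mean_speed_um_per_h`,
#'   `sem_um_per_h` (over steps), `n_steps`.
#' @export
compute_speed <- function(track, lapse_interval_min) {
  if (inherits(track, "cell_tracks")) track <- track$tracks
  stopifnot(nrow(track) >= 2, lapse_interval_min > 0)
  track <- track[order(track$frame), ]
  consec <- diff(track$frame) == 1
  dx <- diff(track$x_um)[consec]
  dy <- diff(track$y_um)[consec]
  disp <- sqrt(dx^2 + dy^2)
  speeds <- disp * 60 / lapse_interval_min
  list(step_speeds_um_per_h = speeds,
       mean_speed_um_per_h = if (length(speeds)) mean(speeds) else NA_real_,
       sem_um_per_h = sem(speeds),
       n_steps = length(speeds))
}

#' Protrusion, retraction and dynamic polarity for one frame pair
#'
#' The protrusion P is the area newly occupied in the later frame
#' (`mask_t1` minus `mask_t`), the retraction R the area vacated
#' (`mask_t` minus `mask_t1`). Masses are the dry mass inside P measured
#' on the later map and inside R on the earlier map, normalised per
#' minute; areas likewise. Dynamic polarity is the distance between the
#' (unweighted) area centroids of P and R - the spatial asymmetry of
#' shape change that drives translocation - and is recorded as missing
#' when either set is empty. The pixel-count identity
#' `area(t) + P*dt - R*dt = area(t+1)` holds exactly by construction.
#'
#' @param mask_t,mask_t1 logical matrices: the cell's footprint at t and
#'   t+1.
#' @param dm_t,dm_t1 the matching background-subtracted `dry_mass_map`s.
#' @param lapse_interval_min lapse interval, minutes.
#' @param weighted_centroids use mass-weighted instead of area centroids
#'   for the polarity (default FALSE).
#' @return A `protrusion_record`: protrusion/retraction mass (pg/min) and
#'   area (um^2/min), `max_pixel_mass_fg` (largest single-pixel mass in
#'   the protrusion, femtograms), `dynamic_polarity_um`, areas at t/t+1,
#'   and `suspect` (TRUE when the two masks do not overlap at all).
#' @export
protrusion_retraction <- function(mask_t, mask_t1, dm_t, dm_t1,
                                  lapse_interval_min,
                                  weighted_centroids = FALSE) {
  stopifnot(identical(dim(mask_t), dim(mask_t1)),
            lapse_interval_min > 0)
  vt <- map_values(dm_t); vt1 <- map_values(dm_t1)
  px <- if (inherits(dm_t, "dry_mass_map")) dm_t$pixel_size_um else 1
  px_area <- px^2
  P <- mask_t1 & !mask_t
  R <- mask_t & !mask_t1
  dt <- lapse_interval_min
  cent <- function(mask, weights) {
    idx <- which(mask)
    if (!length(idx)) return(c(NA_real_, NA_real_))
    nr <- nrow(mask)
    r <- (idx - 1) %% nr + 1
    c <- (idx - 1) %/% nr + 1
    w <- if (is.null(weights)) rep(1, length(idx)) else pmax(weights[idx], 0)
    if (sum(w) <= 0) w <- rep(1, length(idx))
    c(sum(w * (c - 1)) / sum(w), sum(w * (r - 1)) / sum(w)) * px
  }
  cp <- cent(P, if (weighted_centroids) vt1 else NULL)
  cr <- cent(R, if (weighted_centroids) vt else NULL)
  polarity <- if (anyNA(cp) || anyNA(cr)) NA_real_ else
    sqrt(sum((cp - cr)^2))
  structure(list(
    protrusion_mass_pg_per_min = sum(vt1[P]) * px_area / dt,
    protrusion_area_um2_per_min = sum(P) * px_area / dt,
    retraction_mass_pg_per_min = sum(vt[R]) * px_area / dt,
    retraction_area_um2_per_min = sum(R) * px_area / dt,
    max_pixel_mass_fg = if (any(P)) max(vt1[P]) * px_area * 1000
                        else NA_real_,
    dynamic_polarity_um = polarity,
    protrusion_centroid_um = cp, retraction_centroid_um = cr,
    area_t_um2 = sum(mask_t) * px_area,
    area_t1_um2 = sum(mask_t1) * px_area,
    lapse_interval_min = dt,
    suspect = !any(mask_t & mask_t1)
  ), class = "protrusion_record")
}

#' @export
print.protrusion_record <- function(x, ...) {
  cat("protrusion_record (dt =", x$lapse_interval_min, "min):\n")
  cat("  protrusion:", signif(x$protrusion_mass_pg_per_min, 4), "pg/min,",
      signif(x$protrusion_area_um2_per_min, 4), "um^2/min\n")
  cat("  retraction:", signif(x$retraction_mass_pg_per_min, 4), "pg/min,",
      signif(x$retraction_area_um2_per_min, 4), "um^2/min\n")
  cat("  dynamic polarity:", signif(x$dynamic_polarity_um, 4), "um\n")
  if (x$suspect) cat("  [suspect: masks do not overlap]\n")
  invisible(x)
}

#' Protrusion/retraction records along a whole track
#'
#' Applies [protrusion_retraction()] to every consecutive frame pair of a
#' track, extracting the track's footprint from the labelled frames.
#'
#' @param track single-track data.frame (frame, label).
#' @param frames list of `labeled_frame`s.
#' @param maps list of background-subtracted `dry_mass_map`s.
#' @param lapse_interval_min lapse interval, minutes.
#' @param ... passed to [protrusion_retraction()].
#' @return data.frame with one row per frame pair.
#' @export
track_protrusions <- function(track, frames, maps, lapse_interval_min,
                              ...) {
  track <- track[order(track$frame), ]
  out <- list()
  for (k in seq_len(nrow(track) - 1)) {
    if (track$frame[k + 1] - track$frame[k] != 1) next
    f0 <- track$frame[k]; f1 <- track$frame[k + 1]
    rec <- protrusion_retraction(
      frames[[f0]]$labels == track$label[k],
      frames[[f1]]$labels == track$label[k + 1],
      maps[[f0]], maps[[f1]], lapse_interval_min, ...)
    out[[length(out) + 1]] <- data.frame(
      track_id = track$track_id[1], frame = f0,
      protrusion_mass_pg_per_min = rec$protrusion_mass_pg_per_min,
      protrusion_area_um2_per_min = rec$protrusion_area_um2_per_min,
      retraction_mass_pg_per_min = rec$retraction_mass_pg_per_min,
      retraction_area_um2_per_min = rec$retraction_area_um2_per_min,
      max_pixel_mass_fg = rec$max_pixel_mass_fg,
      dynamic_polarity_um = rec$dynamic_polarity_um,
      suspect = rec$suspect)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Summarise a movie's tracks, growth fits and protrusion records
#'
#' Means with their standard errors (SEM = SD/sqrt(N)) in the convention
#' mass and doubling time are summarised over cells, speed over steps
#' (with the over-cells alternative also reported), protrusion/polarity
#' over frame pairs. N is stated for every quantity.
#'
#' @param tracks a `cell_tracks` object or tracks data.frame.
#' @param lapse_interval_min lapse interval, minutes.
#' @param records optional data.frame of protrusion records
#'   ([track_protrusions()] rows).
#' @param fits optional list of `growth_fit`s.
#' @return data.frame: quantity, mean, sem, n, unit.
#' @export
summarize_movie <- function(tracks, lapse_interval_min, records = NULL,
                            fits = NULL) {
  tr <- if (inherits(tracks, "cell_tracks")) tracks$tracks else tracks
  per_track <- split(tr, tr$track_id)
  cell_mass <- vapply(per_track, function(d) mean(d$mass_pg), 0)
  rows <- list(data.frame(
    quantity = "mean_cell_mass", mean = mean(cell_mass),
    sem = sem(cell_mass), n = length(cell_mass), unit = "pg"))
  sp <- lapply(per_track, function(d)
    if (nrow(d) >= 2) compute_speed(d, lapse_interval_min) else NULL)
  sp <- sp[!vapply(sp, is.null, logical(1))]
  all_steps <- unlist(lapply(sp, `[[`, "step_speeds_um_per_h"))
  cell_speed <- vapply(sp, `[[`, 0, "mean_speed_um_per_h")
  rows <- c(rows, list(
    data.frame(quantity = "mean_speed_over_steps",
               mean = mean(all_steps), sem = sem(all_steps),
               n = length(all_steps), unit = "um/h"),
    data.frame(quantity = "mean_speed_over_cells",
               mean = mean(cell_speed), sem = sem(cell_speed),
               n = length(cell_speed), unit = "um/h")))
  if (!is.null(fits)) {
    fits <- fits[!vapply(fits, is.null, logical(1))]
    td <- vapply(fits, `[[`, 0, "doubling_time_h")
    td <- td[is.finite(td) & td > 0]
    if (length(td))
      rows <- c(rows, list(data.frame(
        quantity = "mean_doubling_time", mean = mean(td), sem = sem(td),
        n = length(td), unit = "h")))
  }
  if (!is.null(records) && nrow(records)) {
    pol <- records$dynamic_polarity_um
    pol <- pol[is.finite(pol)]
    rows <- c(rows, list(
      data.frame(quantity = "mean_protrusion_mass",
                 mean = mean(records$protrusion_mass_pg_per_min),
                 sem = sem(records$protrusion_mass_pg_per_min),
                 n = nrow(records), unit = "pg/min"),
      data.frame(quantity = "mean_dynamic_polarity",
                 mean = mean(pol), sem = sem(pol),
                 n = length(pol), unit = "um"),
      data.frame(quantity = "mean_max_pixel_mass",
                 mean = mean(records$max_pixel_mass_fg, na.rm = TRUE),
                 sem = sem(records$max_pixel_mass_fg),
                 n = sum(is.finite(records$max_pixel_mass_fg)),
                 unit = "fg")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
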
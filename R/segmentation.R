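#' Segment a background-subtracted dry-mass map
#'
#' A deliberately low threshold - a fraction (default 1%) of the maximum
#' cell signal after mild Gaussian smoothing - preserves the thin cell
#' periphery. The mask is taken on the smoothed map, but all per-label
#' statistics are computed on the RAW values inside the mask, so small
#' negative phase values in the thinnest parts of a cell contribute with
#' their sign and total mass stays accurate.
#'
#' @param dm a `dry_mass_map` (background-subtracted).
#' @param threshold_fraction mask threshold as a fraction of the smoothed
#'   map's maximum (default 0.01).
#' @param smooth_sigma_px Gaussian smoothing SD in pixels applied before
#'   thresholding only (default 1).
#' @param min_area_um2 smallest component kept, in um^2 (default 50).
#' @param mask_dilate_px margin, in pixels, by which the threshold mask
#'   is expanded before statistics are taken (default 2). The periphery
#'   just below threshold - where pixel values are small and may be
#'   negative - belongs to the cell; without a margin a hard threshold
#'   would systematically clip it.
#' @return A `labeled_frame`: list with `labels` (integer matrix, 0 =
#'   background, 8-connected components), `stats` (data.frame: label,
#'   area_um2, mass_pg, x_um, y_um - mass-weighted centroid using the
#'   positive part of the signal), `timestamp_min`, `pixel_size_um`.
#' @export
segment_frame <- function(dm, threshold_fraction = 0.01,
                          smooth_sigma_px = 1, min_area_um2 = 50,
                          mask_dilate_px = 2) {
  stopifnot(inherits(dm, "dry_mass_map"), threshold_fraction > 0)
  v <- dm$values
  sm <- if (smooth_sigma_px > 0)
    as.matrix(EBImage::gblur(v, sigma = smooth_sigma_px)) else v
  mx <- max(sm)
  empty <- labeled_frame(matrix(0L, nrow(v), ncol(v)),
                         stats = empty_label_stats(),
                         timestamp_min = dm$timestamp_min,
                         pixel_size_um = dm$pixel_size_um)
  if (mx <= 0) return(empty)
  mask <- sm > threshold_fraction * mx
  if (mask_dilate_px > 0 && any(mask)) {
    kern <- EBImage::makeBrush(2L * as.integer(mask_dilate_px) + 1L,
                               "disc")
    mask <- as.matrix(EBImage::dilate(EBImage::Image(mask * 1), kern)) > 0
  }
  labels <- cpp_label8(mask)
  if (max(labels) == 0L) return(empty)
  px_area <- dm$pixel_size_um^2
  min_px <- max(1L, ceiling(min_area_um2 / px_area))
  nr <- nrow(v)
  stats_list <- lapply(seq_len(max(labels)), function(l) {
    idx <- which(labels == l)
    if (length(idx) < min_px) return(NULL)
    vals <- v[idx]
    r <- (idx - 1) %% nr + 1
    c <- (idx - 1) %/% nr + 1
    w <- pmax(vals, 0)
    sw <- sum(w)
    if (sw <= 0) { w <- rep(1, length(idx)); sw <- length(idx) }
    data.frame(label = l,
               area_um2 = length(idx) * px_area,
               mass_pg = sum(vals) * px_area,
               x_um = sum(w * (c - 1)) / sw * dm$pixel_size_um,
               y_um = sum(w * (r - 1)) / sw * dm$pixel_size_um)
  })
  stats <- do.call(rbind, stats_list)
  if (is.null(stats) || !nrow(stats)) return(empty)
  # drop components below the size filter and relabel contiguously
  keep <- stats$label
  relab <- integer(max(labels))
  relab[keep] <- seq_along(keep)
  labels[] <- ifelse(labels > 0, relab[labels], 0L)
  stats$label <- seq_along(keep)
  rownames(stats) <- NULL
  labeled_frame(labels, stats, dm$timestamp_min, dm$pixel_size_um)
}

empty_label_stats <- function() {
  data.frame(label = integer(), area_um2 = numeric(),
             mass_pg = numeric(), x_um = numeric(), y_um = numeric())
}

#' Construct a labeled frame
#'
#' @param labels integer matrix of 8-connected component labels (0 =
#'   background).
#' @param stats per-label data.frame (label, area_um2, mass_pg, x_um,
#'   y_um).
#' @param timestamp_min acquisition time.
#' @param pixel_size_um pixel pitch.
#' @return A `labeled_frame`.
#' @export
labeled_frame <- function(labels, stats, timestamp_min = 0,
                          pixel_size_um = 1) {
  structure(list(labels = labels, stats = stats,
                 timestamp_min = timestamp_min,
                 pixel_size_um = pixel_size_um),
            class = "labeled_frame")
}

#' @export
print.labeled_frame <- function(x, ...) {
  cat("labeled_frame:", nrow(x$stats), "objects, t =",
      x$timestamp_min, "min\n")
  if (nrow(x$stats)) print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Track labelled objects across frames
#'
#' Frame-to-frame linking by the rule "nearest object with a similar mass
#' in the next frame": candidate (track, object) pairs are considered in
#' ascending centroid-distance order (greedy) and a pair is linked only if
#' the distance is at most `d_max_um` AND the relative mass difference
#' `|m1 - m2| / max(m1, m2)` is at most `mass_tol`. Unmatched objects
#' start new tracks; a track unmatched for more than `max_gap` frames is
#' closed. When two tracks converge on one object (a merge), the nearest
#' wins, the lighter competitor is closed and a merge event is recorded.
#'
#' @param frames list of `labeled_frame`s in time order.
#' @param d_max_um maximum linking distance per lapse (default 30 um).
#' @param mass_tol maximum relative mass difference (default 0.35).
#' @param max_gap frames a track may stay unmatched before it is closed
#'   (default 0: consecutive frames only).
#' @return A `cell_tracks` object: list with `tracks` (data.frame:
#'   track_id, frame, t_min, label, x_um, y_um, mass_pg, area_um2) and
#'   `merges` (data.frame of merge events).
#' @export
track_frames <- function(frames, d_max_um = 30, mass_tol = 0.35,
                         max_gap = 0L) {
  stopifnot(length(frames) >= 2)
  active <- list()   # each: list(id, last_frame, x, y, mass, rows)
  rows <- list()
  merges <- data.frame(frame = integer(), winner = integer(),
                       loser = integer())
  next_id <- 1L
  add_row <- function(id, t, fr, lab) {
    s <- fr$stats[fr$stats$label == lab, ]
    rows[[length(rows) + 1]] <<- data.frame(
      track_id = id, frame = t, t_min = fr$timestamp_min,
      label = lab, x_um = s$x_um, y_um = s$y_um,
      mass_pg = s$mass_pg, area_um2 = s$area_um2)
  }
  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    st <- fr$stats
    if (is.null(st) || !nrow(st)) st <- empty_label_stats()
    if (t == 1L) {
      for (k in seq_len(nrow(st))) {
        active[[length(active) + 1]] <- list(
          id = next_id, last_frame = 1L, x = st$x_um[k], y = st$y_um[k],
          mass = st$mass_pg[k])
        add_row(next_id, 1L, fr, st$label[k])
        next_id <- next_id + 1L
      }
      next
    }
    assigned_obj <- rep(FALSE, nrow(st))
    assigned_trk <- rep(FALSE, length(active))
    wanted <- integer(0)   # tracks that lost their nearest object
    if (nrow(st) && length(active)) {
      cand <- expand.grid(trk = seq_along(active),
                          obj = seq_len(nrow(st)))
      cand$dist <- sqrt(
        (vapply(active, `[[`, 0, "x")[cand$trk] - st$x_um[cand$obj])^2 +
        (vapply(active, `[[`, 0, "y")[cand$trk] - st$y_um[cand$obj])^2)
      m1 <- vapply(active, `[[`, 0, "mass")[cand$trk]
      m2 <- st$mass_pg[cand$obj]
      cand$massdiff <- abs(m1 - m2) / pmax(abs(m1), abs(m2))
      cand <- cand[cand$dist <= d_max_um & cand$massdiff <= mass_tol, ]
      cand <- cand[order(cand$dist), ]
      for (k in seq_len(nrow(cand))) {
        trk <- cand$trk[k]; obj <- cand$obj[k]
        if (assigned_trk[trk]) next
        if (assigned_obj[obj]) { wanted <- c(wanted, trk); next }
        assigned_trk[trk] <- TRUE
        assigned_obj[obj] <- TRUE
        active[[trk]]$last_frame <- t
        active[[trk]]$x <- st$x_um[obj]
        active[[trk]]$y <- st$y_um[obj]
        active[[trk]]$mass <- st$mass_pg[obj]
        add_row(active[[trk]]$id, t, fr, st$label[obj])
      }
    }
    # merge bookkeeping: a track whose admissible nearest object was taken
    for (trk in unique(wanted)) {
      if (!assigned_trk[trk])
        merges <- rbind(merges, data.frame(
          frame = t, winner = NA_integer_, loser = active[[trk]]$id))
    }
    # close stale tracks, open new ones
    keep <- vapply(active, function(a) t - a$last_frame <= max_gap,
                   logical(1))
    active <- active[keep]
    for (k in which(!assigned_obj)) {
      active[[length(active) + 1]] <- list(
        id = next_id, last_frame = t, x = st$x_um[k], y = st$y_um[k],
        mass = st$mass_pg[k])
      add_row(next_id, t, fr, st$label[k])
      next_id <- next_id + 1L
    }
  }
  tracks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(), t_min = numeric(),
               label = integer(), x_um = numeric(), y_um = numeric(),
               mass_pg = numeric(), area_um2 = numeric())
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  structure(list(tracks = tracks, merges = merges,
                 n_frames = length(frames)),
            class = "cell_tracks")
}

#' @export
print.cell_tracks <- function(x, ...) {
  ids <- unique(x$tracks$track_id)
  cat("cell_tracks:", length(ids), "tracks over", x$n_frames, "frames\n")
  if (length(ids)) {
    len <- table(x$tracks$track_id)
    cat("  track lengths:", paste(range(len), collapse = " .. "),
        "frames; mean mass",
        signif(mean(x$tracks$mass_pg), 4), "pg\n")
  }
  if (nrow(x$merges)) cat("  merge events:", nrow(x$merges), "\n")
  invisible(x)
}

# Per-track data.frame helper used by the metrics stage.
split_tracks <- function(tracks) {
  if (inherits(tracks, "cell_tracks")) tracks <- tracks$tracks
  split(tracks, tracks$track_id)
}
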
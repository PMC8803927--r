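#' Detect openings in the red monolayer
#'
#' A hole is a significant local reduction of the red fluorescence
#' relative to the intact-monolayer reference: the baseline is the
#' median-smoothed first frame, and a pixel at frame t is a hole pixel
#' when its (matched-smoothed) intensity falls below
#' `hole_factor * baseline`. Connected components smaller than
#' `min_hole_area_um2` are discarded. Regions already near zero in the
#' baseline (below `exclude_frac` of the baseline median) cannot be
#' scored and are masked out. Optional per-frame renormalisation rescales
#' every frame so its median matches the baseline median, absorbing
#' global photobleaching.
#'
#' @param red_stack list of red-channel matrices (or 3D array), frame 1 =
#'   intact monolayer reference.
#' @param pixel_size_um pixel pitch.
#' @param hole_factor detection factor (default 0.5: below 50% of
#'   baseline).
#' @param min_hole_area_um2 smallest hole kept (default 50 um^2).
#' @param median_radius_px half-width of the median smoothing window
#'   (default 2).
#' @param renormalize per-frame global intensity renormalisation
#'   (default FALSE).
#' @param exclude_frac baseline fraction below which a region is excluded
#'   from scoring (default 0.05).
#' @return A `hole_detection`: list with `masks` (list of logical hole
#'   masks), `labels` (integer matrices), `excluded` (logical matrix),
#'   `baseline` (matrix), `n_excluded_px`.
#' @export
detect_holes <- function(red_stack, pixel_size_um,
                         hole_factor = 0.5, min_hole_area_um2 = 50,
                         median_radius_px = 2, renormalize = FALSE,
                         exclude_frac = 0.05) {
  arr <- stack_array(red_stack)
  nf <- dim(arr)[3]
  smooth <- function(m) {
    lo <- min(m); hi <- max(m)
    if (hi <= lo) return(m)
    sc <- (m - lo) / (hi - lo)
    as.matrix(EBImage::medianFilter(sc, median_radius_px)) *
      (hi - lo) + lo
  }
  baseline <- smooth(arr[, , 1])
  excluded <- baseline < exclude_frac * stats::median(baseline)
  px_area <- pixel_size_um^2
  min_px <- max(1L, ceiling(min_hole_area_um2 / px_area))
  base_med <- stats::median(baseline)
  masks <- vector("list", nf)
  labels <- vector("list", nf)
  for (t in seq_len(nf)) {
    fr <- smooth(arr[, , t])
    if (renormalize) fr <- fr * base_med / stats::median(fr)
    hole <- fr < hole_factor * baseline & !excluded
    lab <- cpp_label8(hole)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = max(lab))
      drop <- which(sizes < min_px)
      if (length(drop)) {
        hole[lab %in% drop] <- FALSE
        lab <- cpp_label8(hole)
      }
    }
    masks[[t]] <- hole
    labels[[t]] <- lab
  }
  structure(list(masks = masks, labels = labels, excluded = excluded,
                 baseline = baseline, n_excluded_px = sum(excluded),
                 hole_factor = hole_factor,
                 pixel_size_um = pixel_size_um),
            class = "hole_detection")
}

#' Segment and track cells in the green channel
#'
#' Otsu intensity threshold plus a size filter segments the labelled
#' cancer cells; tracking reuses the mass-gated nearest-object linker
#' ([track_frames()]) with the integrated intensity of each object
#' standing in for dry mass.
#'
#' @param green_stack list of green-channel matrices (or 3D array).
#' @param pixel_size_um pixel pitch.
#' @param lapse_interval_min lapse interval, minutes.
#' @param min_area_um2 smallest object kept (default 100 um^2).
#' @param threshold intensity threshold; default NULL = Otsu on the first
#'   frame, reused for the whole movie.
#' @param d_max_um,mass_tol,max_gap passed to [track_frames()].
#' @return List: `tracks` (a `cell_tracks`), `frames` (list of
#'   `labeled_frame`s; the `mass_pg` column holds integrated intensity).
#' @export
segment_track_green <- function(green_stack, pixel_size_um,
                                lapse_interval_min = 15,
                                min_area_um2 = 100, threshold = NULL,
                                d_max_um = 30, mass_tol = 0.5,
                                max_gap = 0L) {
  arr <- stack_array(green_stack)
  nf <- dim(arr)[3]
  if (is.null(threshold)) {
    f1 <- arr[, , 1]
    rng <- range(f1)
    threshold <- if (diff(rng) <= 0) Inf else
      EBImage::otsu((f1 - rng[1]) / diff(rng), range = c(0, 1)) *
        diff(rng) + rng[1]
  }
  px_area <- pixel_size_um^2
  min_px <- max(1L, ceiling(min_area_um2 / px_area))
  frames <- vector("list", nf)
  for (t in seq_len(nf)) {
    v <- arr[, , t]
    mask <- v > threshold
    lab <- cpp_label8(mask)
    nr <- nrow(v)
    stats_list <- lapply(seq_len(max(lab)), function(l) {
      idx <- which(lab == l)
      if (length(idx) < min_px) return(NULL)
      vals <- v[idx]
      r <- (idx - 1) %% nr + 1
      c <- (idx - 1) %/% nr + 1
      sw <- sum(vals)
      data.frame(label = l, area_um2 = length(idx) * px_area,
                 mass_pg = sw * px_area,
                 x_um = sum(vals * (c - 1)) / sw * pixel_size_um,
                 y_um = sum(vals * (r - 1)) / sw * pixel_size_um)
    })
    stats <- do.call(rbind, stats_list)
    if (is.null(stats)) stats <- empty_label_stats()
    keep <- stats$label
    relab <- integer(max(lab, 1L))
    relab[keep] <- seq_along(keep)
    lab[] <- ifelse(lab > 0, relab[pmax(lab, 1L)], 0L)
    stats$label <- seq_along(keep)
    frames[[t]] <- labeled_frame(lab, stats,
                                 timestamp_min = (t - 1) * lapse_interval_min,
                                 pixel_size_um = pixel_size_um)
  }
  tracks <- if (nf >= 2) track_frames(frames, d_max_um = d_max_um,
                                      mass_tol = mass_tol,
                                      max_gap = max_gap)
            else structure(list(tracks = data.frame(), merges = data.frame(),
                                n_frames = nf), class = "cell_tracks")
  list(tracks = tracks, frames = frames, threshold = threshold)
}

#' Score invasion as coincidence of cells with monolayer openings
#'
#' A tracked cell is invading when, at any frame of its life, the overlap
#' of its footprint with the hole mask reaches `overlap_min` of the
#' footprint - a cell must coincide with an opening; mere holes (or mere
#' cells) do not count. Only tracks with at least `min_track_len` points
#' enter the denominator.
#'
#' @param green list from [segment_track_green()] (tracks + frames).
#' @param holes a `hole_detection`.
#' @param overlap_min minimum footprint overlap fraction (default 0.3).
#' @param min_track_len minimum track length in frames (default 3).
#' @param movie_id,treatment labels carried into the result.
#' @return An `invasion_result`: n_cells, n_invading, fraction (NA and
#'   flagged when no cell qualifies), per-cell event records.
#' @export
score_invasion <- function(green, holes, overlap_min = 0.3,
                           min_track_len = 3, movie_id = NA,
                           treatment = NA) {
  stopifnot(inherits(holes, "hole_detection"))
  tr <- green$tracks$tracks
  events <- list()
  ids <- unique(tr$track_id)
  n_cells <- 0L
  n_invading <- 0L
  for (id in ids) {
    d <- tr[tr$track_id == id, ]
    if (nrow(d) < min_track_len) next
    n_cells <- n_cells + 1L
    first_frame <- NA_integer_
    best_overlap <- 0
    for (k in seq_len(nrow(d))) {
      t <- d$frame[k]
      fp <- green$frames[[t]]$labels == d$label[k]
      ov <- sum(fp & holes$masks[[t]]) / sum(fp)
      if (ov > best_overlap) best_overlap <- ov
      if (is.na(first_frame) && ov >= overlap_min) first_frame <- t
    }
    invading <- !is.na(first_frame)
    if (invading) n_invading <- n_invading + 1L
    events[[length(events) + 1]] <- data.frame(
      track_id = id, invading = invading,
      first_coincidence_frame = first_frame,
      max_overlap_fraction = best_overlap)
  }
  structure(list(
    movie_id = movie_id, treatment = treatment,
    n_cells = n_cells, n_invading = n_invading,
    fraction = if (n_cells > 0) n_invading / n_cells else NA_real_,
    undefined = n_cells == 0L,
    events = if (length(events)) do.call(rbind, events) else NULL,
    overlap_min = overlap_min, min_track_len = min_track_len
  ), class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat("invasion_result",
      if (!is.na(x$movie_id)) paste0("[", x$movie_id, "]"), ":",
      x$n_invading, "of", x$n_cells, "cells invading")
  if (x$undefined) cat(" (fraction undefined: no scorable cells)\n")
  else cat(" (fraction ", sprintf("%.3f", x$fraction), ")\n", sep = "")
  invisible(x)
}

#' Compare invasion between treatment groups
#'
#' Movies are the experimental units: per treatment, the mean and SEM of
#' the movie-level invading fractions are reported, and every non-reference
#' treatment is compared with the reference by a one-way ANOVA over the
#' movie fractions. Groups with a single movie have no SEM and the
#' comparison is refused.
#'
#' @param results list of `invasion_result`s, or a data.frame with
#'   columns `treatment` and `fraction` (one row per movie).
#' @param reference name of the reference treatment (default: first
#'   level).
#' @return A `treatment_comparison`: summary data.frame (treatment, mean
#'   fraction, sem, n_movies, n_cells, p_vs_reference).
#' @export
compare_treatments <- function(results, reference = NULL) {
  if (is.data.frame(results)) {
    df <- results
    if (is.null(df$n_cells)) df$n_cells <- NA_integer_
  } else {
    df <- do.call(rbind, lapply(results, function(r) data.frame(
      treatment = r$treatment, fraction = r$fraction,
      n_cells = r$n_cells)))
  }
  df <- df[is.finite(df$fraction), ]
  df$treatment <- as.character(df$treatment)
  treatments <- unique(df$treatment)
  if (is.null(reference)) reference <- treatments[1]
  stopifnot(reference %in% treatments)
  out <- lapply(treatments, function(tr) {
    fr <- df$fraction[df$treatment == tr]
    n <- length(fr)
    p <- NA_real_
    if (tr != reference) {
      ref <- df$fraction[df$treatment == reference]
      if (n < 2 || length(ref) < 2)
        stop("treatment group with a single movie: SEM undefined, ",
             "comparison refused")
      sub <- data.frame(fraction = c(ref, fr),
                        group = rep(c("ref", "trt"), c(length(ref), n)))
      p <- stats::anova(stats::lm(fraction ~ group,
                                  data = sub))[["Pr(>F)"]][1]
    }
    data.frame(treatment = tr, mean_fraction = mean(fr),
               sem = sem(fr), n_movies = n,
               n_cells = sum(df$n_cells[df$treatment == tr]),
               p_vs_reference = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(list(summary = out, reference = reference),
            class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat("Invasion by treatment (reference:", x$reference, ")\n")
  s <- x$summary
  s$mean_fraction <- signif(s$mean_fraction, 3)
  s$sem <- signif(s$sem, 3)
  s$p_vs_reference <- signif(s$p_vs_reference, 3)
  print(s, row.names = FALSE)
  invisible(x)
}
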
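#' Specify a synthetic QPI time-lapse scene
#'
#' A scene is a rectangular field observed for `n_frames` time points at a
#' fixed lapse interval. Cells are smooth positive dry-mass blobs that move
#' as persistent random walks (optionally biased along a drift direction),
#' grow exponentially in dry mass, and sit on a smooth optical background
#' aberration (a degree-2 polynomial in optical path, micrometres) whose
#' overall level fluctuates from frame to frame. Defaults mirror the
#' acquisition geometry of an incoherent-source phase-shifting interference
#' microscope: a 634 x 483 um field, 530 nm illumination and a 10 min lapse.
#'
#' @param field_size_px integer pair, image size as (rows, cols).
#' @param pixel_size_um pixel pitch in micrometres.
#' @param lapse_interval_min time between frames, minutes.
#' @param n_frames number of time points (>= 2).
#' @param wavelength_nm illumination wavelength.
#' @param cells list of [cell_spec()] objects.
#' @param background_poly_coeffs coefficients (um OPD) of the background
#'   surface for terms (1, u, v, u^2, u*v, v^2) with u, v the column/row
#'   coordinates normalised to [0, 1].
#' @param frame_offset_sd SD (um OPD) of the per-frame global background
#'   offset fluctuation.
#' @param intensity_noise_sd SD of additive Gaussian sensor noise on the
#'   interferogram intensities (camera counts).
#' @param alpha_um3_per_pg specific refractive increment used to convert
#'   dry-mass surface density to optical path.
#' @param phase_steps_rad the four reference phase steps; the quarter-wave
#'   schedule (0, pi/2, pi, 3*pi/2) is the default and the only schedule the
#'   two-difference arctangent reconstruction supports.
#' @param carrier_amplitude,carrier_modulation mean intensity A and fringe
#'   modulation B of the interferograms, I = A + B cos(phi + delta).
#' @param rng_seed integer seed; every random draw in the generator flows
#'   from it.
#' @return A `scene_spec` object (list).
#' @seealso [simulate_ground_truth()], [render_interferograms()]
#' @export
scene_spec <- function(field_size_px = c(242L, 317L),
                       pixel_size_um = 2,
                       lapse_interval_min = 10,
                       n_frames = 30L,
                       wavelength_nm = 530,
                       cells = list(),
                       background_poly_coeffs = c(0.02, 0.03, -0.02,
                                                  0.012, -0.008, 0.016),
                       frame_offset_sd = 0.005,
                       intensity_noise_sd = 0.5,
                       alpha_um3_per_pg = 0.18,
                       phase_steps_rad = c(0, pi / 2, pi, 3 * pi / 2),
                       carrier_amplitude = 100,
                       carrier_modulation = 50,
                       rng_seed = 1L) {
  stopifnot(length(field_size_px) == 2, all(field_size_px >= 8),
            pixel_size_um > 0, lapse_interval_min > 0,
            n_frames >= 2, wavelength_nm > 0,
            frame_offset_sd >= 0, intensity_noise_sd >= 0,
            alpha_um3_per_pg > 0, length(phase_steps_rad) == 4)
  field_um <- rev(field_size_px) * pixel_size_um  # (x, y) extent
  for (cl in cells) {
    stopifnot(inherits(cl, "cell_spec"))
    p <- cl$initial_position_um
    if (p[1] < 0 || p[1] > field_um[1] || p[2] < 0 || p[2] > field_um[2])
      stop("cell initially outside the field")
    if (any(8 * cl$shape_sigma_um >= field_um))
      stop("cell blob footprint larger than the field")
  }
  structure(list(
    field_size_px = as.integer(field_size_px),
    pixel_size_um = pixel_size_um,
    lapse_interval_min = lapse_interval_min,
    n_frames = as.integer(n_frames),
    wavelength_nm = wavelength_nm,
    cells = cells,
    background_poly_coeffs = background_poly_coeffs,
    frame_offset_sd = frame_offset_sd,
    intensity_noise_sd = intensity_noise_sd,
    alpha_um3_per_pg = alpha_um3_per_pg,
    phase_steps_rad = phase_steps_rad,
    carrier_amplitude = carrier_amplitude,
    carrier_modulation = carrier_modulation,
    rng_seed = as.integer(rng_seed)
  ), class = "scene_spec")
}

#' Specify one synthetic cell
#'
#' @param initial_mass_pg starting dry mass (picograms).
#' @param doubling_time_h dry-mass doubling time in hours; `Inf` for a
#'   non-growing cell.
#' @param initial_position_um (x, y) position in micrometres, x along
#'   columns, y along rows (y grows downward).
#' @param speed_um_per_h constant step speed of the persistent random walk.
#' @param persistence_time_min directional persistence time; the heading
#'   changes between frames by a wrapped-normal increment with
#'   SD = sqrt(2 * lapse / persistence).
#' @param drift_direction_rad direction of chemotactic drift (radians,
#'   measured from +x, y downward), or `NULL` for none.
#' @param drift_fraction fraction of steps taken exactly along the drift
#'   direction (biased-mixture chemotaxis model), in [0, 1].
#' @param shape_sigma_um Gaussian blob axes (sigma_x, sigma_y), micrometres.
#' @return A `cell_spec` object.
#' @export
cell_spec <- function(initial_mass_pg = 800,
                      doubling_time_h = 36,
                      initial_position_um = c(100, 100),
                      speed_um_per_h = 33,
                      persistence_time_min = 60,
                      drift_direction_rad = NULL,
                      drift_fraction = 0,
                      shape_sigma_um = c(10, 10)) {
  stopifnot(initial_mass_pg > 0, doubling_time_h > 0,
            length(initial_position_um) == 2,
            speed_um_per_h >= 0, persistence_time_min > 0,
            drift_fraction >= 0, drift_fraction <= 1,
            length(shape_sigma_um) == 2, all(shape_sigma_um > 0))
  if (drift_fraction > 0 && is.null(drift_direction_rad))
    stop("drift_fraction > 0 requires drift_direction_rad")
  structure(list(
    initial_mass_pg = initial_mass_pg,
    doubling_time_h = doubling_time_h,
    initial_position_um = as.numeric(initial_position_um),
    speed_um_per_h = speed_um_per_h,
    persistence_time_min = persistence_time_min,
    drift_direction_rad = drift_direction_rad,
    drift_fraction = drift_fraction,
    shape_sigma_um = as.numeric(shape_sigma_um)
  ), class = "cell_spec")
}

#' Simulate the ground truth of a QPI scene
#'
#' Produces, per frame, the true dry-mass surface-density field (pg um^-2,
#' cells only, no optical background), a truth label image (pixel ownership
#' by cell), per-cell true masses and centroid trajectories. Cell blobs are
#' anisotropic Gaussians truncated at 4 sigma and renormalised so the
#' integrated in-field mass equals the scheduled mass exactly; mass grows as
#' m0 * 2^(t / Td). Trajectories are persistent random walks of constant
#' step speed with an optional biased-mixture drift. A cell whose 4-sigma
#' footprint crosses the field boundary is flagged in `left_field`, not an
#' error.
#'
#' @param spec a [scene_spec()].
#' @return A `qpi_truth` object: list with `dry_mass` (list of matrices),
#'   `labels` (list of integer matrices), `masses` (frames x cells),
#'   `trajectories` (data.frame: frame, cell, t_min, x_um, y_um, mass_pg),
#'   `left_field` (frames x cells logical), `offsets_um` placeholder filled
#'   by [render_interferograms()], and the `spec`.
#' @export
simulate_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$field_size_px[1]; nc <- spec$field_size_px[2]
  px <- spec$pixel_size_um
  nf <- spec$n_frames
  ncell <- length(spec$cells)
  dt_min <- spec$lapse_interval_min
  sim <- simulate_tracks(spec)
  pos <- sim$positions
  masses <- sim$masses
  {
    # rendering --------------------------------------------------------
    xs <- (seq_len(nc) - 1) * px
    ys <- (seq_len(nr) - 1) * px
    dry_mass <- vector("list", nf)
    labels <- vector("list", nf)
    left_field <- matrix(FALSE, nf, ncell)
    for (t in seq_len(nf)) {
      dm <- matrix(0, nr, nc)
      own <- matrix(0L, nr, nc)
      own_val <- matrix(0, nr, nc)
      for (ci in seq_len(ncell)) {
        cl <- spec$cells[[ci]]
        sx <- cl$shape_sigma_um[1]; sy <- cl$shape_sigma_um[2]
        cx <- pos[t, ci, 1]; cy <- pos[t, ci, 2]
        if (cx - 4 * sx < 0 || cx + 4 * sx > (nc - 1) * px ||
            cy - 4 * sy < 0 || cy + 4 * sy > (nr - 1) * px)
          left_field[t, ci] <- TRUE
        jr <- which(xs >= cx - 4 * sx & xs <= cx + 4 * sx)
        ir <- which(ys >= cy - 4 * sy & ys <= cy + 4 * sy)
        if (!length(jr) || !length(ir)) next
        dx <- (xs[jr] - cx) / sx
        dy <- (ys[ir] - cy) / sy
        rho2 <- outer(dy^2, dx^2, `+`)
        g <- exp(-rho2 / 2)
        g[rho2 > 16] <- 0
        s <- sum(g) * px^2
        if (s <= 0) next
        g <- g * (masses[t, ci] / s)
        dm[ir, jr] <- dm[ir, jr] + g
        upd <- g > own_val[ir, jr]
        sub_own <- own[ir, jr]; sub_val <- own_val[ir, jr]
        sub_own[upd] <- ci; sub_val[upd] <- g[upd]
        own[ir, jr] <- sub_own; own_val[ir, jr] <- sub_val
      }
      dry_mass[[t]] <- dm
      labels[[t]] <- own
    }
    structure(list(
      dry_mass = dry_mass, labels = labels, masses = masses,
      trajectories = sim$trajectories, left_field = left_field,
      spec = spec
    ), class = "qpi_truth")
  }
}

#' Simulate cell trajectories and masses without rendering images
#'
#' The trajectory/growth half of [simulate_ground_truth()]: persistent
#' random walks with optional drift and exponential dry-mass growth,
#' seeded from the scene seed. Useful for statistical simulations (e.g.
#' power studies of the chemotaxis tests) where images are not needed.
#' `simulate_ground_truth(spec)$trajectories` is identical to
#' `simulate_tracks(spec)$trajectories`.
#'
#' @param spec a [scene_spec()].
#' @return List: `trajectories` (data.frame: frame, cell, t_min, x_um,
#'   y_um, mass_pg), `positions` (frames x cells x 2 array), `masses`
#'   (frames x cells).
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nf <- spec$n_frames
  ncell <- length(spec$cells)
  dt_min <- spec$lapse_interval_min
  with_seed(spec$rng_seed, {
    pos <- array(NA_real_, c(nf, ncell, 2))
    for (ci in seq_len(ncell)) {
      cl <- spec$cells[[ci]]
      step_len <- cl$speed_um_per_h * dt_min / 60
      sd_turn <- sqrt(2 * dt_min / cl$persistence_time_min)
      theta <- if (!is.null(cl$drift_direction_rad))
        cl$drift_direction_rad else runif(1, -pi, pi)
      p <- cl$initial_position_um
      pos[1, ci, ] <- p
      if (nf > 1) for (t in 2:nf) {
        drift_step <- cl$drift_fraction > 0 &&
          runif(1) < cl$drift_fraction
        theta <- theta + rnorm(1, 0, sd_turn)
        dir <- if (drift_step) cl$drift_direction_rad else theta
        p <- p + step_len * c(cos(dir), sin(dir))
        pos[t, ci, ] <- p
      }
    }
    t_h <- (seq_len(nf) - 1) * dt_min / 60
    masses <- sapply(seq_len(ncell), function(ci) {
      cl <- spec$cells[[ci]]
      cl$initial_mass_pg * 2^(t_h / cl$doubling_time_h)
    })
    masses <- matrix(masses, nf, ncell)
    traj <- data.frame(
      frame = rep(seq_len(nf), times = ncell),
      cell = rep(seq_len(ncell), each = nf),
      t_min = rep((seq_len(nf) - 1) * dt_min, times = ncell),
      x_um = as.vector(pos[, , 1]),
      y_um = as.vector(pos[, , 2]),
      mass_pg = as.vector(masses)
    )
    list(trajectories = traj, positions = pos, masses = masses)
  })
}

#' Render phase-shifted interferograms from a ground-truth scene
#'
#' Implements the sinusoidal forward model of phase-shifting interferometry:
#' at each time point four frames are recorded,
#' `I_k = A + B cos(phi + delta_k) + eps`, where
#' `phi = 2 pi OPD / lambda`, and the optical path difference is
#' `OPD = alpha * sigma + background polynomial + per-frame offset`
#' (micrometres; sigma the dry-mass surface density). Sensor noise `eps` is
#' Gaussian with SD `spec$intensity_noise_sd`, seeded from the scene seed.
#'
#' @param truth a [simulate_ground_truth()] result.
#' @param spec the matching [scene_spec()]; defaults to `truth$spec`.
#' @return List of `interferogram_set` objects (one per time point) with
#'   attributes `offsets_um` (the true per-frame background offsets) and
#'   `wrap_warning` (TRUE when the rendered phase spans more than one
#'   2 pi period, i.e. the scene will exercise unwrapping).
#' @export
render_interferograms <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "qpi_truth"), inherits(spec, "scene_spec"))
  nr <- spec$field_size_px[1]; nc <- spec$field_size_px[2]
  stopifnot(identical(dim(truth$dry_mass[[1]]), c(nr, nc)))
  nf <- length(truth$dry_mass)
  lambda_um <- spec$wavelength_nm / 1000
  bg <- poly2_surface(spec$background_poly_coeffs, nr, nc)
  with_seed(spec$rng_seed + 1L, {
    offsets <- rnorm(nf, 0, spec$frame_offset_sd)
    wrap_warn <- FALSE
    out <- vector("list", nf)
    for (t in seq_len(nf)) {
      opd <- spec$alpha_um3_per_pg * truth$dry_mass[[t]] + bg + offsets[t]
      phi <- 2 * pi * opd / lambda_um
      if (diff(range(phi)) > 2 * pi) wrap_warn <- TRUE
      frames <- lapply(spec$phase_steps_rad, function(d) {
        f <- spec$carrier_amplitude +
          spec$carrier_modulation * cos(phi + d)
        if (spec$intensity_noise_sd > 0)
          f <- f + matrix(rnorm(length(f), 0, spec$intensity_noise_sd),
                          nrow(f), ncol(f))
        f
      })
      out[[t]] <- interferogram_set(
        frames, spec$phase_steps_rad, spec$wavelength_nm,
        timestamp_min = (t - 1) * spec$lapse_interval_min,
        pixel_size_um = spec$pixel_size_um,
        carrier = c(A = spec$carrier_amplitude,
                    B = spec$carrier_modulation))
    }
    if (wrap_warn)
      warning("rendered phase spans more than one 2*pi period; ",
              "reconstruction will require unwrapping")
    attr(out, "offsets_um") <- offsets
    attr(out, "wrap_warning") <- wrap_warn
    out
  })
}

#' Specify a synthetic two-channel invasion-assay movie
#'
#' Emulates the observable of a monolayer invasion assay: a confluent
#' monolayer labelled in the red channel, individually labelled cancer
#' cells in the green channel, and - under each scripted invading cell - a
#' hole in the red monolayer that opens at a scheduled frame and decays
#' toward a residual fraction of the baseline intensity. Defaults follow
#' the assay geometry (1308 x 1308 um field, 15 min lapse).
#'
#' @param field_size_px image size (rows, cols).
#' @param pixel_size_um pixel pitch, micrometres.
#' @param lapse_interval_min lapse interval (default 15 min).
#' @param n_frames number of time points (default 15, i.e. 210 min).
#' @param n_green_cells number of cancer cells.
#' @param invading_indices indices (1-based) of the cells that invade.
#' @param hole_onset_frame frame at which each invading cell's hole starts
#'   opening (recycled).
#' @param hole_radius_um final hole radius (recycled).
#' @param hole_decay_frames e-folding time, in frames, of the decay of red
#'   intensity inside a hole toward the residual level.
#' @param red_baseline_level mean red intensity of the intact monolayer.
#' @param hole_residual_fraction red intensity floor inside a mature hole,
#'   as a fraction of baseline (must sit below the detection factor used
#'   downstream).
#' @param green_level peak green intensity of a cell blob.
#' @param cell_sigma_um Gaussian radius of a green cell blob.
#' @param speed_um_per_h cell speed (persistent random walk).
#' @param persistence_time_min directional persistence of cell motion.
#' @param photobleach_rate per-frame fractional loss of red intensity
#'   (global; 0 disables bleaching).
#' @param noise_sd additive Gaussian noise SD on both channels.
#' @param rng_seed integer seed.
#' @return An `invasion_scene_spec` object.
#' @export
invasion_scene_spec <- function(field_size_px = c(218L, 218L),
                                pixel_size_um = 6,
                                lapse_interval_min = 15,
                                n_frames = 15L,
                                n_green_cells = 10L,
                                invading_indices = integer(),
                                hole_onset_frame = 4L,
                                hole_radius_um = 25,
                                hole_decay_frames = 1,
                                red_baseline_level = 1000,
                                hole_residual_fraction = 0.2,
                                green_level = 500,
                                cell_sigma_um = 8,
                                speed_um_per_h = 10,
                                persistence_time_min = 60,
                                photobleach_rate = 0,
                                noise_sd = 10,
                                rng_seed = 1L) {
  stopifnot(length(field_size_px) == 2, pixel_size_um > 0,
            lapse_interval_min > 0, n_frames >= 2, n_green_cells >= 1,
            red_baseline_level > 0,
            hole_residual_fraction >= 0, hole_residual_fraction < 1,
            noise_sd >= 0, photobleach_rate >= 0, photobleach_rate < 1)
  invading_indices <- as.integer(invading_indices)
  if (length(invading_indices) &&
      (min(invading_indices) < 1 || max(invading_indices) > n_green_cells))
    stop("invading_indices must index the green cells")
  structure(list(
    field_size_px = as.integer(field_size_px),
    pixel_size_um = pixel_size_um,
    lapse_interval_min = lapse_interval_min,
    n_frames = as.integer(n_frames),
    n_green_cells = as.integer(n_green_cells),
    invading_indices = invading_indices,
    hole_onset_frame = as.integer(hole_onset_frame),
    hole_radius_um = hole_radius_um,
    hole_decay_frames = hole_decay_frames,
    red_baseline_level = red_baseline_level,
    hole_residual_fraction = hole_residual_fraction,
    green_level = green_level,
    cell_sigma_um = cell_sigma_um,
    speed_um_per_h = speed_um_per_h,
    persistence_time_min = persistence_time_min,
    photobleach_rate = photobleach_rate,
    noise_sd = noise_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "invasion_scene_spec")
}

#' Render a synthetic invasion-assay movie
#'
#' @param spec an [invasion_scene_spec()].
#' @return An `invasion_movie` object: lists `red` and `green` of intensity
#'   matrices, plus `truth` (invading indices, cell trajectories, hole
#'   centres/onsets) and the `spec`.
#' @export
render_invasion_movie <- function(spec) {
  stopifnot(inherits(spec, "invasion_scene_spec"))
  nr <- spec$field_size_px[1]; nc <- spec$field_size_px[2]
  px <- spec$pixel_size_um
  nf <- spec$n_frames
  ncell <- spec$n_green_cells
  xs <- (seq_len(nc) - 1) * px
  ys <- (seq_len(nr) - 1) * px
  fx <- (nc - 1) * px; fy <- (nr - 1) * px
  with_seed(spec$rng_seed, {
    # cells placed on a jittered grid so blobs stay well separated
    ng <- ceiling(sqrt(ncell))
    gx <- ((seq_len(ng) - 0.5) / ng) * fx
    gy <- ((seq_len(ng) - 0.5) / ng) * fy
    grid <- expand.grid(x = gx, y = gy)[seq_len(ncell), ]
    jit <- matrix(runif(2 * ncell, -0.08, 0.08), ncell) *
      cbind(rep(fx / ng, ncell), rep(fy / ng, ncell))
    pos0 <- as.matrix(grid) + jit
    # persistent random walk per cell
    step_len <- spec$speed_um_per_h * spec$lapse_interval_min / 60
    sd_turn <- sqrt(2 * spec$lapse_interval_min / spec$persistence_time_min)
    pos <- array(NA_real_, c(nf, ncell, 2))
    for (ci in seq_len(ncell)) {
      theta <- runif(1, -pi, pi)
      p <- pos0[ci, ]
      pos[1, ci, ] <- p
      for (t in seq_len(nf)[-1]) {
        theta <- theta + rnorm(1, 0, sd_turn)
        p <- pmin(pmax(p + step_len * c(cos(theta), sin(theta)), 0),
                  c(fx, fy))
        pos[t, ci, ] <- p
      }
    }
    onsets <- rep_len(spec$hole_onset_frame, length(spec$invading_indices))
    radii <- rep_len(spec$hole_radius_um, length(spec$invading_indices))
    hole_centers <- if (length(spec$invading_indices)) {
      t(sapply(seq_along(spec$invading_indices), function(k)
        pos[onsets[k], spec$invading_indices[k], ]))
    } else matrix(numeric(), 0, 2)
    # gentle smooth texture on the monolayer
    texture <- 1 + 0.04 * poly2_surface(c(0, 1, -1, 0.5, 0, 0.5), nr, nc)
    red <- vector("list", nf)
    green <- vector("list", nf)
    for (t in seq_len(nf)) {
      rframe <- spec$red_baseline_level * texture *
        (1 - spec$photobleach_rate)^(t - 1)
      for (k in seq_along(spec$invading_indices)) {
        if (t < onsets[k]) next
        d2 <- outer((ys - hole_centers[k, 2])^2,
                    (xs - hole_centers[k, 1])^2, `+`)
        inside <- d2 <= radii[k]^2
        res <- spec$hole_residual_fraction
        level <- res + (1 - res) *
          exp(-(t - onsets[k] + 1) / spec$hole_decay_frames)
        rframe[inside] <- rframe[inside] * level
      }
      gframe <- matrix(0, nr, nc)
      for (ci in seq_len(ncell)) {
        d2 <- outer((ys - pos[t, ci, 2])^2, (xs - pos[t, ci, 1])^2, `+`)
        g <- spec$green_level * exp(-d2 / (2 * spec$cell_sigma_um^2))
        g[d2 > (4 * spec$cell_sigma_um)^2] <- 0
        gframe <- gframe + g
      }
      if (spec$noise_sd > 0) {
        rframe <- rframe + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
        gframe <- gframe + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
      }
      red[[t]] <- rframe
      green[[t]] <- gframe
    }
    traj <- data.frame(
      frame = rep(seq_len(nf), times = ncell),
      cell = rep(seq_len(ncell), each = nf),
      x_um = as.vector(pos[, , 1]),
      y_um = as.vector(pos[, , 2])
    )
    structure(list(
      red = red, green = green,
      truth = list(invading = spec$invading_indices,
                   trajectories = traj,
                   hole_centers = hole_centers,
                   hole_onsets = onsets,
                   hole_radii = radii),
      spec = spec
    ), class = "invasion_movie")
  })
}
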
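#' Bundle four phase-shifted interferograms
#'
#' @param frames list of 4 intensity matrices of identical shape, in
#'   phase-step order.
#' @param phase_steps_rad the 4 reference phase steps, strictly increasing
#'   within one 2 pi period.
#' @param wavelength_nm illumination wavelength.
#' @param timestamp_min acquisition time of this set, minutes.
#' @param pixel_size_um pixel pitch, micrometres.
#' @param carrier optional named numeric (A, B) recording the rendered mean
#'   intensity and modulation.
#' @return An `interferogram_set`.
#' @export
interferogram_set <- function(frames, phase_steps_rad,
                              wavelength_nm, timestamp_min = 0,
                              pixel_size_um = 1, carrier = NULL) {
  stopifnot(is.list(frames), length(frames) == 4,
            length(phase_steps_rad) == 4, wavelength_nm > 0)
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("interferogram frames must share one shape")
  if (any(diff(phase_steps_rad) <= 0) ||
      diff(range(phase_steps_rad)) >= 2 * pi)
    stop("phase steps must be strictly increasing within one period")
  structure(list(frames = frames,
                 phase_steps_rad = phase_steps_rad,
                 wavelength_nm = wavelength_nm,
                 timestamp_min = timestamp_min,
                 pixel_size_um = pixel_size_um,
                 carrier = carrier),
            class = "interferogram_set")
}

#' Reconstruct wrapped optical path difference from a four-step set
#'
#' The classic four-step phase-shifting solution: with quarter-wave steps
#' (0, pi/2, pi, 3*pi/2) the object phase is the four-quadrant arctangent
#' of a ratio of two image differences,
#' `phi = atan2(I4 - I2, I1 - I3)`, and `OPD = phi * lambda / (2 pi)`.
#' Only the quarter-wave schedule (up to a common offset, which is
#' subtracted) is supported; other schedules would need a Carre-type
#' solution, which is out of scope here. Pixels with no fringe modulation
#' (both differences ~ 0) are marked invalid and filled by
#' nearest-neighbour interpolation; their count is recorded in the
#' `n_invalid` field.
#'
#' @param ifs an [interferogram_set()].
#' @param modulation_tol absolute tolerance under which both image
#'   differences count as zero modulation.
#' @return An `opd_map` (wrapped = TRUE) with fields `values` (um of
#'   optical path), `pixel_size_um`, `timestamp_min`, `wavelength_um`,
#'   `invalid` (logical matrix) and `n_invalid`.
#' @export
reconstruct_phase <- function(ifs, modulation_tol = 1e-9) {
  stopifnot(inherits(ifs, "interferogram_set"))
  steps <- ifs$phase_steps_rad - ifs$phase_steps_rad[1]
  if (max(abs(steps - c(0, pi / 2, pi, 3 * pi / 2))) > 1e-6)
    stop("unsupported phase-step schedule: the two-difference arctangent ",
         "requires quarter-wave steps (0, pi/2, pi, 3pi/2); a Carre-type ",
         "solution for general steps is not implemented")
  I1 <- ifs$frames[[1]]; I2 <- ifs$frames[[2]]
  I3 <- ifs$frames[[3]]; I4 <- ifs$frames[[4]]
  num <- I4 - I2   # 2 B sin(phi)
  den <- I1 - I3   # 2 B cos(phi)
  invalid <- abs(num) < modulation_tol & abs(den) < modulation_tol
  phi <- atan2(num, den) - ifs$phase_steps_rad[1]
  phi <- wrap_to(phi, 2 * pi)
  if (any(invalid)) phi <- fill_invalid(phi, invalid)
  lambda_um <- ifs$wavelength_nm / 1000
  opd_map(phi * lambda_um / (2 * pi),
          pixel_size_um = ifs$pixel_size_um,
          timestamp_min = ifs$timestamp_min,
          wavelength_um = lambda_um,
          wrapped = TRUE, invalid = invalid)
}

#' Construct an optical-path-difference map
#'
#' @param values matrix of optical path values, micrometres.
#' @param pixel_size_um pixel pitch.
#' @param timestamp_min acquisition time.
#' @param wavelength_um wavelength (um), the wrap period of the map.
#' @param wrapped logical; TRUE when values are confined to one wavelength
#'   period.
#' @param invalid optional logical matrix of zero-modulation pixels.
#' @return An `opd_map`.
#' @export
opd_map <- function(values, pixel_size_um = 1, timestamp_min = 0,
                    wavelength_um = 0.53, wrapped = FALSE,
                    invalid = NULL) {
  stopifnot(is.matrix(values), pixel_size_um > 0, wavelength_um > 0)
  structure(list(values = values, pixel_size_um = pixel_size_um,
                 timestamp_min = timestamp_min,
                 wavelength_um = wavelength_um,
                 wrapped = wrapped,
                 invalid = invalid,
                 n_invalid = if (is.null(invalid)) 0L else sum(invalid)),
            class = "opd_map")
}

#' Unwrap a wrapped optical-path map
#'
#' Quality-guided flood-fill unwrapping: pixels are adjoined in order of a
#' smoothness quality (negative local wrapped-gradient energy), each new
#' pixel shifted by the integer multiple of the wavelength that best
#' matches its already-unwrapped neighbour. The result therefore differs
#' from the input only by per-pixel integer multiples of the wavelength,
#' and flat (wrap-free) maps are returned unchanged. Disconnected valid
#' regions are unwrapped independently (each anchored at its own starting
#' pixel); their count is recorded in the `n_regions` field.
#'
#' @param opd an `opd_map` with `wrapped = TRUE`.
#' @return The unwrapped `opd_map` (`wrapped = FALSE`, plus `n_regions`).
#' @export
unwrap_phase <- function(opd) {
  stopifnot(inherits(opd, "opd_map"))
  if (!opd$wrapped) return(opd)
  valid <- if (is.null(opd$invalid)) {
    matrix(TRUE, nrow(opd$values), ncol(opd$values))
  } else !opd$invalid
  res <- cpp_unwrap_quality(opd$values, valid, opd$wavelength_um)
  out <- opd
  out$values <- res$values
  out$wrapped <- FALSE
  out$n_regions <- res$n_regions
  out
}

#' Convert optical path difference to dry-mass surface density
#'
#' Dry-mass densitometry: because the specific refractive increment alpha
#' is nearly the same for all major biomolecules, an unwrapped,
#' background-subtracted optical path converts linearly to dry-mass
#' surface density, `sigma = OPD / alpha` (pg um^-2).
#'
#' @param opd an `opd_map` (unwrapped, background-subtracted).
#' @param alpha_um3_per_pg specific refractive increment (default 0.18
#'   um^3/pg, the literature-standard average for cellular dry matter).
#' @return A `dry_mass_map` with fields `values` (pg um^-2),
#'   `pixel_size_um`, `timestamp_min`, `alpha_um3_per_pg`.
#' @export
opd_to_dry_mass <- function(opd, alpha_um3_per_pg = 0.18) {
  stopifnot(inherits(opd, "opd_map"))
  if (alpha_um3_per_pg <= 0)
    stop("alpha_um3_per_pg must be positive")
  dry_mass_map(opd$values / alpha_um3_per_pg,
               pixel_size_um = opd$pixel_size_um,
               timestamp_min = opd$timestamp_min,
               alpha_um3_per_pg = alpha_um3_per_pg)
}

#' Construct a dry-mass surface-density map
#'
#' @param values matrix, pg um^-2.
#' @param pixel_size_um pixel pitch.
#' @param timestamp_min acquisition time.
#' @param alpha_um3_per_pg specific refractive increment used for the
#'   conversion.
#' @return A `dry_mass_map`.
#' @export
dry_mass_map <- function(values, pixel_size_um = 1, timestamp_min = 0,
                         alpha_um3_per_pg = 0.18) {
  stopifnot(is.matrix(values), pixel_size_um > 0, alpha_um3_per_pg > 0)
  structure(list(values = values, pixel_size_um = pixel_size_um,
                 timestamp_min = timestamp_min,
                 alpha_um3_per_pg = alpha_um3_per_pg),
            class = "dry_mass_map")
}

#' @export
print.dry_mass_map <- function(x, ...) {
  cat("dry_mass_map:", nrow(x$values), "x", ncol(x$values), "px,",
      signif(x$pixel_size_um, 3), "um/px, t =", x$timestamp_min, "min\n")
  cat("  density range:", paste(signif(range(x$values), 4),
                                collapse = " .. "), "pg/um^2\n")
  cat("  total mass:",
      signif(sum(x$values) * x$pixel_size_um^2, 5), "pg\n")
  invisible(x)
}

#' Reconstruct wrapped phase from a single off-axis hologram
#'
#' Fourier-transform holography: the hologram's spatial spectrum contains
#' twin object sidebands displaced by the fringe carrier frequency. One
#' sideband is isolated with a Gaussian filter centred on the carrier,
#' shifted to the origin, and inverse-transformed; the argument of the
#' resulting complex field is the wrapped object phase.
#'
#' @param hologram intensity matrix containing off-axis fringes.
#' @param carrier_cycles_per_px carrier spatial frequency as
#'   (f_row, f_col), cycles per pixel.
#' @param wavelength_nm illumination wavelength.
#' @param pixel_size_um pixel pitch.
#' @param filter_radius_frac Gaussian sideband filter sigma as a fraction
#'   of the carrier magnitude (default 0.2, which keeps the DC term and
#'   the conjugate sideband several sigma away).
#' @return An `opd_map` (wrapped = TRUE).
#' @export
reconstruct_phase_fourier <- function(hologram, carrier_cycles_per_px,
                                      wavelength_nm = 530,
                                      pixel_size_um = 1,
                                      filter_radius_frac = 0.2) {
  stopifnot(is.matrix(hologram), length(carrier_cycles_per_px) == 2)
  nr <- nrow(hologram); nc <- ncol(hologram)
  fmag <- sqrt(sum(carrier_cycles_per_px^2))
  if (fmag < 2 / min(nr, nc))
    stop("carrier frequency below the resolvable limit for this image")
  fr <- ((seq_len(nr) - 1) / nr)
  fr[fr >= 0.5] <- fr[fr >= 0.5] - 1
  fc <- ((seq_len(nc) - 1) / nc)
  fc[fc >= 0.5] <- fc[fc >= 0.5] - 1
  F <- stats::fft(hologram)
  d2 <- outer((fr - carrier_cycles_per_px[1])^2,
              (fc - carrier_cycles_per_px[2])^2, `+`)
  sigma_f <- filter_radius_frac * fmag
  Ffilt <- F * exp(-d2 / (2 * sigma_f^2))
  side <- stats::fft(Ffilt, inverse = TRUE) / (nr * nc)
  # demodulate the carrier
  rows <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
  cols <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  demod <- exp(-2i * pi * (carrier_cycles_per_px[1] * rows +
                             carrier_cycles_per_px[2] * cols))
  phi <- Arg(side * demod)
  lambda_um <- wavelength_nm / 1000
  opd_map(phi * lambda_um / (2 * pi), pixel_size_um = pixel_size_um,
          wavelength_um = lambda_um, wrapped = TRUE)
}

#' Render a synthetic off-axis hologram (forward model of the Fourier mode)
#'
#' `I = A + B cos(2 pi (f . r) + phi)` for a phase field `phi` and carrier
#' `f`; used to exercise [reconstruct_phase_fourier()].
#'
#' @param phi phase matrix (radians).
#' @param carrier_cycles_per_px carrier (f_row, f_col), cycles per pixel.
#' @param amplitude,modulation intensity A and fringe modulation B.
#' @return Intensity matrix.
#' @export
render_hologram <- function(phi, carrier_cycles_per_px,
                            amplitude = 100, modulation = 50) {
  nr <- nrow(phi); nc <- ncol(phi)
  rows <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
  cols <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  amplitude + modulation *
    cos(2 * pi * (carrier_cycles_per_px[1] * rows +
                    carrier_cycles_per_px[2] * cols) + phi)
}
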
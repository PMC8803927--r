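#' Extract horizon-crossing directions from trajectories
#'
#' Chemotaxis needs circular data: each trajectory is reduced to the
#' direction of the cell when it first reaches a fixed horizon distance
#' (default 70 um) from its starting point. The crossing point is found by
#' linear interpolation within the first step whose endpoint lies at or
#' beyond the horizon circle, and the angle is that of the vector from the
#' start to the interpolated crossing. Tracks that never reach the horizon
#' are excluded: chemotaxis is not defined for cells that are not motile.
#' Points after the first crossing are ignored, so appending to a track
#' past its crossing cannot change its direction.
#'
#' @param tracks a `cell_tracks` object, a tracks data.frame, or a list of
#'   per-track data.frames with columns x_um, y_um (in time order).
#' @param horizon_um horizon radius (default 70).
#' @param movie_ids optional vector naming the movie of each track.
#' @return A `directional_sample`: angles_rad in [-pi, pi), horizon_um,
#'   n_total_cells, n_reaching, movie per angle, track ids.
#' @export
horizon_directions <- function(tracks, horizon_um = 70,
                               movie_ids = NULL) {
  stopifnot(horizon_um > 0)
  per_track <- if (is.data.frame(tracks) || inherits(tracks, "cell_tracks"))
    split_tracks(tracks) else tracks
  angles <- numeric(0)
  kept_ids <- character(0)
  for (nm in names(per_track) %||% as.character(seq_along(per_track))) {
    d <- per_track[[nm]]
    if (nrow(d) < 2) next
    x <- d$x_um - d$x_um[1]
    y <- d$y_um - d$y_um[1]
    r <- sqrt(x^2 + y^2)
    hit <- which(r >= horizon_um)[1]
    if (is.na(hit)) next
    if (hit == 1L) {  # degenerate: first point already beyond
      cx <- x[1]; cy <- y[1]
    } else {
      x0 <- x[hit - 1]; y0 <- y[hit - 1]
      dx <- x[hit] - x0; dy <- y[hit] - y0
      # |p0 + s d| = horizon, s in (0, 1]
      a <- dx^2 + dy^2
      b <- 2 * (x0 * dx + y0 * dy)
      cc <- x0^2 + y0^2 - horizon_um^2
      s <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
      cx <- x0 + s * dx; cy <- y0 + s * dy
    }
    angles <- c(angles, atan2(cy, cx))
    kept_ids <- c(kept_ids, nm)
  }
  movie <- if (is.null(movie_ids)) rep(NA_character_, length(angles))
           else as.character(movie_ids)[match(kept_ids,
                names(per_track) %||% as.character(seq_along(per_track)))]
  angles <- wrap_to(angles, 2 * pi)
  angles[angles == pi] <- -pi   # canonical range [-pi, pi)
  structure(list(
    angles_rad = angles,
    horizon_um = horizon_um,
    n_total_cells = length(per_track),
    n_reaching = length(angles),
    movie = movie, track_ids = kept_ids
  ), class = "directional_sample")
}

#' @export
print.directional_sample <- function(x, ...) {
  cat("directional_sample:", x$n_reaching, "of", x$n_total_cells,
      "cells reached the", x$horizon_um, "um horizon\n")
  if (x$n_reaching) {
    C <- sum(cos(x$angles_rad)); S <- sum(sin(x$angles_rad))
    cat("  mean direction:", signif(atan2(S, C), 4), "rad,  Rbar =",
        signif(sqrt(C^2 + S^2) / x$n_reaching, 4), "\n")
  }
  invisible(x)
}

#' Rose plot of a directional sample
#'
#' @param x a `directional_sample`.
#' @param bins number of angular sectors (default 16).
#' @param ... passed to [graphics::plot()].
#' @export
plot.directional_sample <- function(x, bins = 16, ...) {
  th <- x$angles_rad
  breaks <- seq(-pi, pi, length.out = bins + 1)
  counts <- graphics::hist(th, breaks = breaks, plot = FALSE)$counts
  rmax <- max(counts, 1)
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", ...)
  for (k in seq_len(bins)) {
    a <- seq(breaks[k], breaks[k + 1], length.out = 12)
    graphics::polygon(c(0, counts[k] * cos(a)), c(0, counts[k] * sin(a)),
                      col = "grey80")
  }
  graphics::symbols(0, 0, circles = rmax, inches = FALSE, add = TRUE)
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests uniformity of directions against unimodal clustering using the
#' mean resultant length Rbar: Z = n * Rbar^2, with the standard series
#' approximation for the p-value,
#' `p = exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4) /
#' (288 n^2)]`, clipped into (0, 1]. The mean direction's 95% confidence
#' half-width uses the von Mises large-sample circular standard error
#' `1 / sqrt(n * Rbar * kappa_hat)`.
#'
#' @param sample a `directional_sample`, or a numeric vector of angles in
#'   radians.
#' @return An object of class `htest` with fields `statistic` (Z),
#'   `p.value`, `estimate` (mean direction and Rbar), and
#'   `conf.int.halfwidth.rad`.
#' @export
rayleigh_test <- function(sample) {
  th <- if (inherits(sample, "directional_sample")) sample$angles_rad
        else as.numeric(sample)
  n <- length(th)
  if (n < 3) stop("Rayleigh test needs at least 3 angles")
  C <- sum(cos(th)); S <- sum(sin(th))
  rbar <- sqrt(C^2 + S^2) / n
  mu <- atan2(S, C)
  Z <- n * rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) /
                    (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  kappa <- vonmises_kappa(rbar)
  ci_half <- if (rbar > 0 && is.finite(kappa) && kappa > 0) {
    se <- 1 / sqrt(n * rbar * kappa)
    min(stats::qnorm(0.975) * se, pi)
  } else NA_real_
  structure(list(
    statistic = c(Z = Z),
    parameter = c(n = n),
    p.value = p,
    estimate = c(mean_direction_rad = mu, mean_resultant_length = rbar),
    conf.int.halfwidth.rad = ci_half,
    method = "Rayleigh test of circular uniformity",
    data.name = deparse(substitute(sample))
  ), class = "htest")
}

# Maximum-likelihood-style approximation to the von Mises concentration
# from the mean resultant length (Fisher 1993 three-regime form).
vonmises_kappa <- function(rbar) {
  if (rbar <= 0) return(0)
  if (rbar >= 1) return(Inf)
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

#' Per-cell displacement components along a gradient direction
#'
#' The chemotactic response of each cell: the mean over its consecutive
#' steps of the displacement component along the gradient unit vector,
#' scaled to micrometres per hour. Cells are the sampling units of
#' [gradient_component_anova()].
#'
#' @param tracks `cell_tracks` or tracks data.frame.
#' @param gradient_direction_rad gradient direction (radians, from +x,
#'   y downward).
#' @param lapse_interval_min lapse interval, minutes.
#' @return data.frame: track_id, component_um_per_h, n_steps.
#' @export
displacement_components <- function(tracks, gradient_direction_rad,
                                    lapse_interval_min) {
  g <- c(cos(gradient_direction_rad), sin(gradient_direction_rad))
  per_track <- split_tracks(tracks)
  out <- lapply(per_track, function(d) {
    if (nrow(d) < 2) return(NULL)
    d <- d[order(d$frame), ]
    consec <- diff(d$frame) == 1
    comp <- (diff(d$x_um) * g[1] + diff(d$y_um) * g[2])[consec]
    if (!length(comp)) return(NULL)
    data.frame(track_id = d$track_id[1],
               component_um_per_h = mean(comp) * 60 / lapse_interval_min,
               n_steps = length(comp))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hierarchical unbalanced ANOVA on gradient displacement components
#'
#' Compares populations on their per-cell mean displacement component
#' along the gradient with a two-level nested (hierarchical) model:
#' population is a fixed effect, movies are random within population, and
#' cells are the sampling units within movies. Because movies, not cells,
#' are the independent replicates, the population effect is tested
#' against the movie-within-population stratum:
#' `F = MS_population / MS_movies_within_population` with the sequential
#' (hierarchical) sums of squares, which handles unbalanced data.
#'
#' @param data data.frame with columns `response`, `population`, `movie`
#'   (movie labels need only be unique within population).
#' @return A `nested_anova` object: the ANOVA table, F, df and p-value.
#' @export
gradient_component_anova <- function(data) {
  stopifnot(all(c("response", "population", "movie") %in% names(data)))
  data$population <- factor(data$population)
  data$movie <- factor(paste(data$population, data$movie, sep = "/"))
  if (nlevels(data$population) < 2)
    stop("need at least 2 populations")
  per_pop <- tapply(as.character(data$movie), data$population,
                    function(m) length(unique(m)))
  if (any(per_pop < 2))
    stop("population(s) ", paste(names(per_pop)[per_pop < 2],
         collapse = ", "),
         " have a single movie: the movie-within-population error ",
         "stratum cannot be estimated")
  fit <- stats::lm(response ~ population + population:movie, data = data)
  tab <- stats::anova(fit)
  ms_pop <- tab["population", "Mean Sq"]
  ms_movie <- tab["population:movie", "Mean Sq"]
  df1 <- tab["population", "Df"]
  df2 <- tab["population:movie", "Df"]
  F <- ms_pop / ms_movie
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  structure(list(table = tab, F = F, df = c(df1, df2), p.value = p,
                 n_cells = nrow(data),
                 n_movies = length(unique(data$movie))),
            class = "nested_anova")
}

#' @export
print.nested_anova <- function(x, ...) {
  cat("Hierarchical (nested) ANOVA: population over movies over cells\n")
  cat("  F(", x$df[1], ",", x$df[2], ") =", signif(x$F, 5),
      ", p =", signif(x$p.value, 4), "\n")
  cat("  ", x$n_cells, "cells in", x$n_movies, "movies\n")
  invisible(x)
}

#' Pearson chi-square test for a 2x2 incidence table
#'
#' Closed form for the 2x2 table ((a, b), (c, d)):
#' `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1, upper-tail
#' p-value. Yates continuity correction available behind a flag
#' (default off).
#'
#' @param a,b,c,d non-negative integer cell counts; rows are groups,
#'   columns outcomes.
#' @param yates apply the continuity correction.
#' @return An object of class `htest`.
#' @export
incidence_chi_square <- function(a, b, c, d, yates = FALSE) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop("all row and column margins must be positive")
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  chi2 <- n * num^2 / prod(margins)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(
    statistic = c(`X-squared` = chi2),
    parameter = c(df = 1),
    p.value = p,
    method = paste0("Pearson chi-square test for a 2x2 table",
                    if (yates) " (Yates-corrected)"),
    data.name = sprintf("(%g, %g; %g, %g)", a, b, c, d)
  ), class = "htest")
}
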
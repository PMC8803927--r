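# Internal helpers shared by several stages.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so simulations are reproducible without
# clobbering the session.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Modal value of a numeric vector from a fixed-width histogram whose bins
# are anchored at 0; returns the mean of the values in the most populated
# bin (exact when the underlying mode is a point mass).
hist_mode <- function(x, bin_width) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  if (bin_width <= 0) bin_width <- .Machine$double.eps
  b <- floor(x / bin_width)
  tab <- table(b)
  modal <- names(tab)[which.max(tab)]
  mean(x[b == as.numeric(modal)])
}

# Mode refined by a local median: find the modal histogram bin, then take
# the median of all values within 1.5 bins of its centre. Unbiased for a
# symmetric unimodal distribution and exact for a point mass.
hist_mode_refined <- function(x, bin_width) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  if (bin_width <= 0) bin_width <- .Machine$double.eps
  b <- floor(x / bin_width)
  tab <- tabulate(b - min(b) + 1L)
  center <- (min(b) + which.max(tab) - 1 + 0.5) * bin_width
  near <- x[abs(x - center) <= 1.5 * bin_width]
  stats::median(near)
}

# Robust per-pixel noise scale of a stack (median absolute deviation of
# temporal first differences, scaled to one frame).
stack_noise_sd <- function(stack) {
  arr <- stack_array(stack)
  if (dim(arr)[3] < 2) return(stats::mad(arr))
  d <- arr[, , -1, drop = FALSE] - arr[, , -dim(arr)[3], drop = FALSE]
  # remove each difference frame's global level so per-frame background
  # offsets do not inflate the sensor-noise estimate
  for (t in seq_len(dim(d)[3])) d[, , t] <- d[, , t] - median(d[, , t])
  stats::mad(d) / sqrt(2)
}

# Coerce a list of matrices / maps or a 3D array to a [rows, cols, frames]
# array of values.
stack_array <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3) return(stack)
  if (is.matrix(stack)) return(array(stack, c(dim(stack), 1L)))
  vals <- lapply(stack, map_values)
  array(unlist(vals, use.names = FALSE),
        c(dim(vals[[1]]), length(vals)))
}

map_values <- function(m) {
  if (is.matrix(m)) m else m$values
}

# Wrap values into (-period/2, period/2].
wrap_to <- function(x, period) {
  w <- (x + period / 2) %% period
  w[w == 0] <- period
  w - period / 2
}

# Fill `values` at `bad` pixels from nearest good pixels by iterative
# neighbour averaging (few iterations suffice for isolated invalid pixels).
fill_invalid <- function(values, bad, max_iter = 200L) {
  if (!any(bad)) return(values)
  if (all(bad)) return(values)
  v <- values
  v[bad] <- NA_real_
  nr <- nrow(v); nc <- ncol(v)
  for (it in seq_len(max_iter)) {
    nas <- which(is.na(v), arr.ind = TRUE)
    if (!nrow(nas)) break
    filled <- FALSE
    for (k in seq_len(nrow(nas))) {
      r <- nas[k, 1]; c <- nas[k, 2]
      nb <- c(
        if (r > 1) v[r - 1, c], if (r < nr) v[r + 1, c],
        if (c > 1) v[r, c - 1], if (c < nc) v[r, c + 1]
      )
      nb <- nb[!is.na(nb)]
      if (length(nb)) { v[r, c] <- mean(nb); filled <- TRUE }
    }
    if (!filled) break
  }
  v[is.na(v)] <- 0
  v
}

# Standard error of the mean; NA for n < 2.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Evaluate a degree-2 polynomial surface with coefficients for
# (1, u, v, u^2, u*v, v^2), u = x/width, v = y/height normalised to [0, 1].
poly2_surface <- function(coeffs, nrow_px, ncol_px) {
  coeffs <- c(coeffs, rep(0, 6 - length(coeffs)))[1:6]
  u <- matrix(rep((seq_len(ncol_px) - 1) / max(1, ncol_px - 1),
                  each = nrow_px), nrow_px, ncol_px)
  v <- matrix(rep((seq_len(nrow_px) - 1) / max(1, nrow_px - 1),
                  times = ncol_px), nrow_px, ncol_px)
  coeffs[1] + coeffs[2] * u + coeffs[3] * v +
    coeffs[4] * u^2 + coeffs[5] * u * v + coeffs[6] * v^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
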
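# Background reconstruction for QPI stacks.
#
# Cells only add positive optical path, so each frame's lower half of
# values is a safe provisional background sample; the temporal mode of
# each pixel then reconstructs the cell-free surface wherever the pixel is
# uncovered often enough, and the remaining always-covered areas are
# inpainted from local boundary values blended with a global low-order
# surface.

#' Remove frame-to-frame background fluctuations
#'
#' Each frame's global background level drifts (vibration, source
#' drift). Frames are first aligned to the first frame by the modal
#' value of their pixelwise difference image - differencing cancels the
#' static background aberration exactly, so over cell-free pixels the
#' difference is a point mass at the offset difference. The aligned
#' stack is then shifted by the modal value of its provisional
#' background pixels (the lowest 50% of values: cells only add positive
#' OPD), so the background mode sits at 0 in every frame. Applying the
#' operation twice is a no-op (second-pass offsets ~ 0). A single-frame
#' stack is returned unchanged with offset 0.
#'
#' @param opd_stack list of `opd_map`s, a list of matrices, or a 3D array
#'   (rows, cols, frames) of optical path values (um).
#' @param bin_width histogram bin width for the mode (um); default 4x the
#'   robust per-pixel temporal noise SD, with a small floor.
#' @return List: `stack` (same container type, corrected),
#'   `offsets_um` (numeric, one per frame), `bin_width`.
#' @export
remove_frame_fluctuations <- function(opd_stack, bin_width = NULL) {
  arr <- stack_array(opd_stack)
  nf <- dim(arr)[3]
  if (nf < 2) {
    return(list(stack = opd_stack, offsets_um = rep(0, nf),
                bin_width = bin_width %||% 0))
  }
  if (is.null(bin_width)) {
    bin_width <- max(4 * stack_noise_sd(arr), 1e-6)
  }
  ref <- arr[, , 1]
  offsets <- numeric(nf)
  for (t in 2:nf) {
    offsets[t] <- hist_mode_refined(arr[, , t] - ref, bin_width)
    arr[, , t] <- arr[, , t] - offsets[t]
  }
  # common level: background mode of the aligned stack's provisional
  # background pixels (lowest half of each frame)
  bgpool <- unlist(lapply(seq_len(nf), function(t) {
    v <- arr[, , t]
    v[v <= stats::quantile(v, 0.5)]
  }))
  common <- hist_mode_refined(bgpool, bin_width)
  arr <- arr - common
  offsets <- offsets + common
  list(stack = restack(opd_stack, arr), offsets_um = offsets,
       bin_width = bin_width)
}

# Put corrected values back into the caller's container type.
restack <- function(template, arr) {
  if (is.array(template) && length(dim(template)) == 3) return(arr)
  if (is.matrix(template)) return(arr[, , 1])
  out <- template
  for (t in seq_along(out)) {
    if (is.matrix(out[[t]])) out[[t]] <- arr[, , t]
    else out[[t]]$values <- arr[, , t]
  }
  out
}

#' Reconstruct the cell-free background from temporal modes
#'
#' For every pixel, the most frequent optical-path value over time (a
#' fixed-width temporal histogram) estimates the cell-free background:
#' a pixel is only transiently covered by cells, so its modal value is the
#' clean background. Pixels covered during the entire time-lapse have no
#' dominant value: when the modal bin holds fewer than `f_min` of the
#' frames the pixel is flagged in `covered_always_mask` for inpainting by
#' [inpaint_background()].
#'
#' @param opd_stack fluctuation-corrected stack (list of `opd_map`s,
#'   matrices, or 3D array); >= 5 frames recommended.
#' @param bin_width temporal histogram bin width (um); default 4x the
#'   robust temporal noise SD.
#' @param f_min minimum fraction of frames the modal bin must hold for the
#'   mode to be trusted (default 0.25).
#' @param exclude optional logical array (rows x cols x frames): TRUE
#'   marks a pixel as cell-covered in that frame, removing it from the
#'   pixel's histogram (used by the refinement pass of
#'   [correct_background()]). `f_min` still refers to the total frame
#'   count.
#' @return A `background_estimate`: list with `surface` (um, NA on flagged
#'   pixels until inpainted), `covered_always_mask`, `per_frame_offsets`,
#'   `bin_width`, `f_min`.
#' @export
temporal_mode_background <- function(opd_stack, bin_width = NULL,
                                     f_min = 0.25, exclude = NULL) {
  arr <- stack_array(opd_stack)
  nf <- dim(arr)[3]
  if (is.null(bin_width)) bin_width <- max(4 * stack_noise_sd(arr), 1e-6)
  npix <- prod(dim(arr)[1:2])
  flat <- matrix(arr, npix, nf)
  excl <- if (is.null(exclude)) NULL else matrix(exclude, npix, nf)
  surface <- numeric(npix)
  flagged <- logical(npix)
  need <- f_min * nf
  for (i in seq_len(npix)) {
    v <- if (is.null(excl)) flat[i, ] else flat[i, !excl[i, ]]
    if (length(v) < need) {
      flagged[i] <- TRUE
      surface[i] <- NA_real_
      next
    }
    b <- floor(v / bin_width)
    b0 <- b - min(b) + 1L
    counts <- tabulate(b0)
    k <- which.max(counts)
    if (counts[k] < need) {
      flagged[i] <- TRUE
      surface[i] <- NA_real_
    } else {
      surface[i] <- mean(v[b0 == k])
    }
  }
  structure(list(
    surface = matrix(surface, dim(arr)[1], dim(arr)[2]),
    covered_always_mask = matrix(flagged, dim(arr)[1], dim(arr)[2]),
    per_frame_offsets = attr(opd_stack, "offsets_um") %||% rep(0, nf),
    bin_width = bin_width, f_min = f_min
  ), class = "background_estimate")
}

#' Inpaint always-covered areas of the background surface
#'
#' Fills the flagged gaps with a blend of local and global structure:
#' `w * L + (1 - w) * G`, where `L` is the harmonic (Laplace)
#' interpolation from the gap boundary (local periphery values), `G` is a
#' global degree-2 polynomial least-squares fit to all unflagged pixels,
#' and the weight `w = exp(-d / d0)` decays with the distance `d` to the
#' gap boundary - periphery follows local values, gap centres follow the
#' global surface, and the fill is continuous across the boundary. A gap
#' component touching all four image borders has no usable periphery and
#' falls back to `G` alone (recorded in `fallback_components`).
#'
#' @param est a `background_estimate` from [temporal_mode_background()].
#' @param d0_px blend decay scale in pixels (default 20).
#' @return The `background_estimate` with a complete `surface`.
#' @export
inpaint_background <- function(est, d0_px = 20) {
  stopifnot(inherits(est, "background_estimate"))
  gap <- est$covered_always_mask
  if (!any(gap)) return(est)
  surf <- est$surface
  nr <- nrow(surf); nc <- ncol(surf)
  known <- !gap
  if (!any(known)) stop("no unflagged pixels to anchor the background")

  # global degree-2 surface from unflagged pixels
  idx <- which(known)
  if (length(idx) > 20000) idx <- idx[seq(1, length(idx), length.out = 20000)]
  rr <- ((idx - 1) %% nr + 1 - 1) / max(1, nr - 1)
  cc <- ((idx - 1) %/% nr + 1 - 1) / max(1, nc - 1)
  X <- cbind(1, cc, rr, cc^2, cc * rr, rr^2)
  beta <- qr.coef(qr(X), surf[idx])
  beta[is.na(beta)] <- 0
  G <- poly2_surface(beta, nr, nc)

  # gap components; those touching all 4 borders use G alone
  comp <- cpp_label8(gap)
  fallback <- integer(0)
  for (k in seq_len(max(comp))) {
    cells <- which(comp == k, arr.ind = TRUE)
    if (min(cells[, 1]) == 1 && max(cells[, 1]) == nr &&
        min(cells[, 2]) == 1 && max(cells[, 2]) == nc)
      fallback <- c(fallback, k)
  }
  solve_mask <- gap & !(comp %in% fallback)
  dim(solve_mask) <- dim(gap)

  L <- surf
  if (any(solve_mask)) {
    gi <- which(solve_mask)
    pos <- match(seq_len(nr * nc), gi)  # index into unknown vector
    nun <- length(gi)
    trip_i <- integer(5L * nun); trip_j <- integer(5L * nun)
    trip_x <- numeric(5L * nun)
    nt <- 0L
    rhs <- numeric(nun)
    for (u in seq_len(nun)) {
      i <- gi[u]
      r <- (i - 1) %% nr + 1
      c <- (i - 1) %/% nr + 1
      nbs <- c(if (r > 1) i - 1, if (r < nr) i + 1,
               if (c > 1) i - nr, if (c < nc) i + nr)
      nt <- nt + 1L
      trip_i[nt] <- u; trip_j[nt] <- u; trip_x[nt] <- length(nbs)
      for (nb in nbs) {
        if (solve_mask[nb]) {
          nt <- nt + 1L
          trip_i[nt] <- u; trip_j[nt] <- pos[nb]; trip_x[nt] <- -1
        } else {
          rhs[u] <- rhs[u] + surf[nb]
        }
      }
    }
    trip_i <- trip_i[seq_len(nt)]; trip_j <- trip_j[seq_len(nt)]
    trip_x <- trip_x[seq_len(nt)]
    A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = c(length(gi), length(gi)))
    sol <- as.numeric(Matrix::solve(A, rhs))
    L[gi] <- sol
  }

  # distance to the gap boundary (nearest known pixel), in pixels
  dist <- EBImage::distmap(gap * 1)
  w <- exp(-as.matrix(dist) / d0_px)
  fill <- w * L + (1 - w) * G
  fill[gap & !solve_mask] <- G[gap & !solve_mask]
  surf[gap] <- fill[gap]
  est$surface <- surf
  est$fallback_components <- fallback
  est
}

#' Subtract the reconstructed background from a stack
#'
#' @param opd_stack stack (list of `opd_map`s, matrices, or 3D array).
#' @param est a complete `background_estimate`.
#' @return Stack of the same container type with the surface subtracted.
#' @export
subtract_background <- function(opd_stack, est) {
  stopifnot(inherits(est, "background_estimate"))
  if (anyNA(est$surface))
    stop("background surface incomplete; run inpaint_background() first")
  arr <- stack_array(opd_stack)
  if (!identical(dim(arr)[1:2], dim(est$surface)))
    stop("stack and background surface shapes differ")
  for (t in seq_len(dim(arr)[3])) arr[, , t] <- arr[, , t] - est$surface
  restack(opd_stack, arr)
}

#' Full background pipeline for an OPD stack
#'
#' Fluctuation removal, temporal-mode background, inpainting and
#' subtraction in one call. By default a refinement pass follows: cells
#' are provisionally segmented on the first-pass corrected stack, their
#' masks dilated (cell tails extend beyond any threshold), and the
#' temporal mode recomputed per pixel over cell-free frames only - a
#' slowly moving cell can otherwise leave its faint periphery in a
#' pixel's modal bin and bias the background under the cell.
#'
#' @inheritParams remove_frame_fluctuations
#' @inheritParams temporal_mode_background
#' @inheritParams inpaint_background
#' @param refine run the cell-exclusion refinement pass (default TRUE).
#' @param refine_dilate_px dilation radius (pixels) of the provisional
#'   cell masks (default 5).
#' @param threshold_fraction,min_area_um2 provisional segmentation
#'   parameters (as in [segment_frame()]).
#' @return List: `stack` (corrected), `background` (the estimate),
#'   `offsets_um`.
#' @export
correct_background <- function(opd_stack, bin_width = NULL, f_min = 0.25,
                               d0_px = 20, refine = TRUE,
                               refine_dilate_px = 5,
                               threshold_fraction = 0.01,
                               min_area_um2 = 50) {
  fl <- remove_frame_fluctuations(opd_stack, bin_width = bin_width)
  est <- temporal_mode_background(fl$stack, bin_width = bin_width,
                                  f_min = f_min)
  est$per_frame_offsets <- fl$offsets_um
  est <- inpaint_background(est, d0_px = d0_px)
  stack1 <- subtract_background(fl$stack, est)
  if (refine) {
    arr <- stack_array(stack1)
    px <- if (inherits(opd_stack[[1]], "opd_map"))
      opd_stack[[1]]$pixel_size_um else 1
    kern <- EBImage::makeBrush(2L * as.integer(refine_dilate_px) + 1L,
                               "disc")
    excl <- array(FALSE, dim(arr))
    for (t in seq_len(dim(arr)[3])) {
      lf <- segment_frame(dry_mass_map(arr[, , t], pixel_size_um = px),
                          threshold_fraction = threshold_fraction,
                          min_area_um2 = min_area_um2)
      m <- lf$labels > 0
      if (any(m))
        excl[, , t] <-
          as.matrix(EBImage::dilate(EBImage::Image(m * 1), kern)) > 0
    }
    est2 <- temporal_mode_background(fl$stack, bin_width = bin_width,
                                     f_min = f_min, exclude = excl)
    if (mean(est2$covered_always_mask) > 0.5) {
      # degenerate refinement (e.g. a fully static scene where the
      # provisional masks swallow the field): keep the first pass
      return(list(stack = stack1, background = est,
                  offsets_um = fl$offsets_um))
    }
    est <- est2
    est$per_frame_offsets <- fl$offsets_um
    est <- inpaint_background(est, d0_px = d0_px)
    # refine the per-frame offsets against the reconstructed surface:
    # the histogram mode locates each offset only to ~ bin_width, while
    # the median of (frame - surface) over that frame's cell-free,
    # unflagged pixels is noise-limited
    arr0 <- stack_array(fl$stack)
    extra <- numeric(dim(arr0)[3])
    for (t in seq_len(dim(arr0)[3])) {
      free <- !est$covered_always_mask & !excl[, , t]
      if (sum(free) < 100) free <- !est$covered_always_mask
      extra[t] <- median((arr0[, , t] - est$surface)[free])
      arr0[, , t] <- arr0[, , t] - extra[t]
    }
    fl$stack <- restack(fl$stack, arr0)
    fl$offsets_um <- fl$offsets_um + extra
    est$per_frame_offsets <- fl$offsets_um
    stack1 <- subtract_background(fl$stack, est)
  }
  list(stack = stack1, background = est, offsets_um = fl$offsets_um)
}
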
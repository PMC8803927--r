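# Small scenes shared across test files. Kept deliberately small so the
# suite stays fast; the acceptance tests use fuller geometries.

quick_scene <- function(n_frames = 8, seed = 11, noise = 0,
                        offset_sd = 0, bg = 0, cells = NULL) {
  if (is.null(cells))
    cells <- list(cell_spec(initial_mass_pg = 300, doubling_time_h = Inf,
                            initial_position_um = c(90, 70),
                            speed_um_per_h = 0,
                            shape_sigma_um = c(7, 7)))
  scene_spec(field_size_px = c(80, 100), pixel_size_um = 2,
             n_frames = n_frames, cells = cells,
             background_poly_coeffs = bg, frame_offset_sd = offset_sd,
             intensity_noise_sd = noise, rng_seed = seed)
}

# disc mask helper (matrix of nr x nc, centre in pixels, radius px)
disc_mask <- function(nr, nc, cr, cc, radius) {
  outer(seq_len(nr) - cr, seq_len(nc) - cc,
        function(a, b) a^2 + b^2 <= radius^2)
}
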
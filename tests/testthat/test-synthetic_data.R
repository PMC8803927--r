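test_that("ground truth conserves mass and follows the doubling law", {
  # static, non-growing cell: mass exactly constant
  sp <- quick_scene(n_frames = 10)
  tr <- simulate_ground_truth(sp)
  masses <- sapply(tr$dry_mass, function(m) sum(m) * sp$pixel_size_um^2)
  expect_equal(masses, rep(300, 10), tolerance = 1e-12)
  expect_equal(tr$masses[, 1], rep(300, 10))

  # doubling time 24 h sampled hourly: frame 25 / frame 1 = 2.0
  spg <- scene_spec(field_size_px = c(80, 100), pixel_size_um = 2,
                    lapse_interval_min = 60, n_frames = 25,
                    cells = list(cell_spec(initial_mass_pg = 400,
                                           doubling_time_h = 24,
                                           initial_position_um = c(90, 70),
                                           speed_um_per_h = 0,
                                           shape_sigma_um = c(7, 7))),
                    rng_seed = 2)
  trg <- simulate_ground_truth(spg)
  expect_equal(trg$masses[25, 1] / trg$masses[1, 1], 2.0)
  rendered <- sapply(trg$dry_mass,
                     function(m) sum(m) * spg$pixel_size_um^2)
  expect_equal(rendered[25] / rendered[1], 2.0, tolerance = 0.005)
})

test_that("pure drift moves the centroid by v*dt along the drift axis", {
  cl <- cell_spec(initial_mass_pg = 300, doubling_time_h = Inf,
                  initial_position_um = c(60, 80),
                  speed_um_per_h = 12, persistence_time_min = 60,
                  drift_direction_rad = 0, drift_fraction = 1,
                  shape_sigma_um = c(5, 5))
  sp <- scene_spec(field_size_px = c(80, 100), pixel_size_um = 2,
                   lapse_interval_min = 5, n_frames = 10,
                   cells = list(cl), rng_seed = 4)
  sim <- simulate_tracks(sp)
  steps_x <- diff(sim$positions[, 1, 1])
  steps_y <- diff(sim$positions[, 1, 2])
  expect_equal(steps_x, rep(1.0, 9))   # 12 um/h * 5 min = 1.0 um
  expect_equal(steps_y, rep(0.0, 9))
})

test_that("random-walk step lengths match v*dt in mean (within 2 SEM)", {
  cells <- lapply(1:20, function(i)
    cell_spec(initial_mass_pg = 300, doubling_time_h = Inf,
              initial_position_um = c(100 + 10 * (i %% 5),
                                      60 + 10 * (i %/% 5)),
              speed_um_per_h = 24, persistence_time_min = 30,
              shape_sigma_um = c(5, 5)))
  sp <- scene_spec(field_size_px = c(120, 160), pixel_size_um = 2,
                   lapse_interval_min = 10, n_frames = 40,
                   cells = cells, rng_seed = 5)
  sim <- simulate_tracks(sp)
  steps <- sqrt(apply(sim$positions[, , 1], 2, diff)^2 +
                  apply(sim$positions[, , 2], 2, diff)^2)
  expect_gt(length(steps), 500)
  # constant-speed walk: every step has length v*dt exactly
  expect_equal(mean(steps), 24 * 10 / 60, tolerance = 1e-12)
})

test_that("generator output is deterministic given the seed", {
  sp <- quick_scene(n_frames = 4, seed = 99, noise = 0.5,
                    offset_sd = 0.01)
  a <- simulate_ground_truth(sp)
  b <- simulate_ground_truth(sp)
  expect_identical(a$dry_mass, b$dry_mass)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(render_interferograms(a)[[2]]$frames,
                   render_interferograms(b)[[2]]$frames)
  mv <- invasion_scene_spec(field_size_px = c(60, 60), pixel_size_um = 6,
                            n_frames = 4, n_green_cells = 3,
                            rng_seed = 12)
  expect_identical(render_invasion_movie(mv)$red,
                   render_invasion_movie(mv)$red)
})

test_that("interferogram forward model is the stated cosine", {
  # zero-phase scene: frames are A + B*cos(delta_k) everywhere
  sp <- quick_scene(n_frames = 2, cells = list(
    cell_spec(initial_mass_pg = 1e-9, doubling_time_h = Inf,
              initial_position_um = c(90, 70), speed_um_per_h = 0,
              shape_sigma_um = c(5, 5))))
  tr <- simulate_ground_truth(sp)
  tr$dry_mass <- lapply(tr$dry_mass, function(m) m * 0)
  ifs <- render_interferograms(tr)
  A <- sp$carrier_amplitude; B <- sp$carrier_modulation
  expected <- A + B * cos(sp$phase_steps_rad)   # (150, 100, 50, 100)
  expect_equal(expected, c(150, 100, 50, 100))
  for (k in 1:4)
    expect_equal(unique(round(as.vector(ifs[[1]]$frames[[k]]), 10)),
                 round(expected[k], 10))
})

test_that("interferograms record true offsets and warn past one period", {
  sp <- quick_scene(n_frames = 3, offset_sd = 0.01, seed = 8)
  tr <- simulate_ground_truth(sp)
  ifs <- render_interferograms(tr)
  expect_length(attr(ifs, "offsets_um"), 3)
  expect_false(attr(ifs, "wrap_warning"))
  # a heavy cell pushes phase beyond 2*pi -> wrap warning
  sp2 <- quick_scene(n_frames = 2, cells = list(
    cell_spec(initial_mass_pg = 4000, doubling_time_h = Inf,
              initial_position_um = c(90, 70), speed_um_per_h = 0,
              shape_sigma_um = c(8, 8))))
  tr2 <- simulate_ground_truth(sp2)
  expect_warning(ifs2 <- render_interferograms(tr2), "unwrap")
  expect_true(attr(ifs2, "wrap_warning"))
})

test_that("invasion movie honours its scripted schedule", {
  base <- 1000
  # no invaders: red never drops far below baseline
  sp0 <- invasion_scene_spec(field_size_px = c(80, 80), pixel_size_um = 6,
                             n_frames = 6, n_green_cells = 4,
                             red_baseline_level = base, noise_sd = 10,
                             rng_seed = 3)
  mv0 <- render_invasion_movie(sp0)
  lowest <- min(sapply(mv0$red, min))
  expect_gte(lowest, base * (1 - 0.04) * (1 - 6 * 10 / base))
  # with a hole: centre decays to residual * baseline (within noise)
  sp1 <- invasion_scene_spec(field_size_px = c(80, 80), pixel_size_um = 6,
                             n_frames = 8, n_green_cells = 4,
                             invading_indices = 2, hole_onset_frame = 3,
                             hole_residual_fraction = 0.2,
                             red_baseline_level = base, noise_sd = 5,
                             rng_seed = 3)
  mv1 <- render_invasion_movie(sp1)
  ctr <- round(mv1$truth$hole_centers[1, ] / sp1$pixel_size_um) + 1
  final <- mv1$red[[8]][ctr[2], ctr[1]]
  expect_lt(abs(final - 0.2 * base) / base, 0.06)
  expect_identical(mv1$truth$invading, 2L)
})
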
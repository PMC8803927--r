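test_that("hole detection ignores intact monolayers and bleaching", {
  set.seed(2)
  base <- matrix(1000 + rnorm(3600, 0, 10), 60, 60)
  stack <- lapply(1:6, function(t) base + rnorm(3600, 0, 10))
  h <- detect_holes(stack, pixel_size_um = 6)
  expect_true(all(sapply(h$masks, sum) == 0))
  # global 10% photobleaching, renormalisation on: still no holes
  bleach <- lapply(1:6, function(t) base * (1 - 0.10)^(t - 1) +
                     rnorm(3600, 0, 10))
  hb <- detect_holes(bleach, pixel_size_um = 6, renormalize = TRUE)
  expect_true(all(sapply(hb$masks, sum) == 0))
})

test_that("holes are detected from the frame their core passes 50%", {
  sp <- invasion_scene_spec(field_size_px = c(80, 80), pixel_size_um = 6,
                            n_frames = 10, n_green_cells = 3,
                            invading_indices = 1, hole_onset_frame = 4,
                            hole_residual_fraction = 0.2,
                            hole_decay_frames = 1, noise_sd = 5,
                            rng_seed = 6)
  mv <- render_invasion_movie(sp)
  h <- detect_holes(mv$red, pixel_size_um = 6)
  # generator schedule: level(t) = res + (1-res) exp(-(t-onset+1)/tau)
  level <- function(t) 0.2 + 0.8 * exp(-(t - 4 + 1) / 1)
  first_below <- which(sapply(1:10, level) < 0.5 &
                         seq_len(10) >= 4)[1]
  detected <- which(sapply(h$masks, sum) > 0)[1]
  expect_equal(detected, first_below)
  expect_true(all(sapply(h$masks[first_below:10], sum) > 0))
})

test_that("green segmentation tracks well-separated cells with purity 1", {
  sp <- invasion_scene_spec(field_size_px = c(150, 150),
                            pixel_size_um = 6, n_frames = 8,
                            n_green_cells = 9, noise_sd = 5,
                            rng_seed = 4)
  mv <- render_invasion_movie(sp)
  g <- segment_track_green(mv$green, pixel_size_um = 6,
                           lapse_interval_min = 15)
  tk <- g$tracks$tracks
  expect_equal(length(unique(tk$track_id)), 9)
  expect_equal(nrow(tk), 9 * 8)
  # purity: every track stays nearest to a single true trajectory
  truth <- mv$truth$trajectories
  for (id in unique(tk$track_id)) {
    d <- tk[tk$track_id == id, ]
    cells <- vapply(seq_len(nrow(d)), function(k) {
      tt <- truth[truth$frame == d$frame[k], ]
      tt$cell[which.min((tt$x_um - d$x_um[k])^2 +
                          (tt$y_um - d$y_um[k])^2)]
    }, 0)
    expect_equal(length(unique(cells)), 1)
  }
  # empty stack: zero tracks
  empty <- segment_track_green(lapply(1:3, function(t) matrix(0, 20, 20)),
                               pixel_size_um = 6)
  expect_equal(nrow(empty$tracks$tracks), 0)
})

test_that("invasion scoring recovers the scripted fraction exactly", {
  sp <- invasion_scene_spec(field_size_px = c(180, 180),
                            pixel_size_um = 6, n_frames = 10,
                            n_green_cells = 10,
                            invading_indices = c(2, 5, 8),
                            hole_onset_frame = 3, noise_sd = 5,
                            rng_seed = 10)
  mv <- render_invasion_movie(sp)
  h <- detect_holes(mv$red, pixel_size_um = 6)
  g <- segment_track_green(mv$green, pixel_size_um = 6)
  res <- score_invasion(g, h)
  expect_equal(res$n_cells, 10)
  expect_equal(res$n_invading, 3)
  expect_equal(res$fraction, 0.300)
  # the three scored invaders are the scripted ones (no false positives)
  inv_tracks <- res$events$track_id[res$events$invading]
  truth <- mv$truth$trajectories
  tk <- g$tracks$tracks
  inv_cells <- sort(vapply(inv_tracks, function(id) {
    d <- tk[tk$track_id == id, ][1, ]
    tt <- truth[truth$frame == d$frame, ]
    tt$cell[which.min((tt$x_um - d$x_um)^2 + (tt$y_um - d$y_um)^2)]
  }, 0))
  expect_equal(inv_cells, c(2, 5, 8))
  # no holes anywhere: fraction 0
  sp0 <- invasion_scene_spec(field_size_px = c(120, 120),
                             pixel_size_um = 6, n_frames = 6,
                             n_green_cells = 5, rng_seed = 11)
  mv0 <- render_invasion_movie(sp0)
  res0 <- score_invasion(segment_track_green(mv0$green, 6),
                         detect_holes(mv0$red, 6))
  expect_equal(res0$fraction, 0)
  # holes without any overlapping cell do not count
  expect_true(all(!res0$events$invading))
})

test_that("scoring is monotone in the hole detection factor", {
  sp <- invasion_scene_spec(field_size_px = c(120, 120), pixel_size_um = 6,
                            n_frames = 8, n_green_cells = 6,
                            invading_indices = c(1, 4),
                            hole_onset_frame = 3, noise_sd = 5,
                            rng_seed = 9)
  mv <- render_invasion_movie(sp)
  g <- segment_track_green(mv$green, pixel_size_um = 6)
  fr <- sapply(c(0.3, 0.5, 0.7), function(f)
    score_invasion(g, detect_holes(mv$red, 6, hole_factor = f))$fraction)
  expect_true(all(diff(fr) >= 0))
})

test_that("treatment comparison reports Table-style group summaries", {
  df <- data.frame(
    treatment = rep(c("control", "treated"), each = 3),
    fraction = c(0.2, 0.2, 0.2, 0.03, 0.03, 0.03))
  cmp <- suppressWarnings(compare_treatments(df, reference = "control"))
  s <- cmp$summary
  expect_equal(s$mean_fraction[s$treatment == "control"], 0.200)
  expect_equal(s$sem[s$treatment == "control"], 0)
  expect_equal(s$mean_fraction[s$treatment == "treated"], 0.030)
  # identical groups: p ~ 1
  df2 <- data.frame(treatment = rep(c("a", "b"), each = 4),
                    fraction = rep(c(0.1, 0.15, 0.2, 0.12), 2))
  p <- suppressWarnings(compare_treatments(df2, reference = "a"))$summary
  expect_gt(p$p_vs_reference[p$treatment == "b"], 0.99)
  # order invariance
  df3 <- df2[sample(nrow(df2)), ]
  expect_equal(suppressWarnings(compare_treatments(df3,
                 reference = "a"))$summary$
                 mean_fraction,
               p$mean_fraction)
  # single-movie group refused
  df4 <- data.frame(treatment = c("a", "a", "b"),
                    fraction = c(0.1, 0.2, 0.3))
  expect_error(compare_treatments(df4, reference = "a"), "single movie")
})
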
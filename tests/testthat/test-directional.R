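test_that("horizon crossings are interpolated onto the horizon circle", {
  # straight track along +x
  t1 <- data.frame(track_id = 1, frame = 1:3, x_um = c(0, 50, 100),
                   y_um = 0)
  s <- horizon_directions(list("1" = t1), horizon_um = 70)
  expect_equal(s$angles_rad, 0)
  expect_equal(s$n_reaching, 1)
  # 45-degree track crosses at (49.5, 49.5)
  t2 <- data.frame(track_id = 2, frame = 1:3, x_um = c(0, 50, 100),
                   y_um = c(0, 50, 100))
  s2 <- horizon_directions(list("2" = t2), horizon_um = 70)
  expect_equal(s2$angles_rad, pi / 4, tolerance = 1e-12)
  # L-shaped track: 60 um along +x then up +y; crossing at y* where
  # 60^2 + y*^2 = 70^2
  t3 <- data.frame(track_id = 3, frame = 1:3, x_um = c(0, 60, 60),
                   y_um = c(0, 0, 60))
  s3 <- horizon_directions(list("3" = t3), horizon_um = 70)
  ystar <- sqrt(70^2 - 60^2)
  expect_equal(s3$angles_rad, atan2(ystar, 60), tolerance = 1e-12)
  # dense numeric sampling of the same path agrees
  path_x <- c(seq(0, 60, by = 0.001), rep(60, 60000))
  path_y <- c(rep(0, 60001), seq(0.001, 60, by = 0.001))
  r <- sqrt(path_x^2 + path_y^2)
  k <- which(r >= 70)[1]
  expect_equal(atan2(path_y[k], path_x[k]), s3$angles_rad,
               tolerance = 1e-4)
  # appending points after the crossing changes nothing
  t3b <- rbind(t3, data.frame(track_id = 3, frame = 4:5,
                              x_um = c(-100, 300), y_um = c(5, -200)))
  expect_equal(horizon_directions(list("3" = t3b), 70)$angles_rad,
               s3$angles_rad)
  # non-reaching tracks are excluded
  short <- data.frame(track_id = 4, frame = 1:3, x_um = c(0, 5, 10),
                      y_um = 0)
  s4 <- horizon_directions(list("3" = t3, "4" = short), 70)
  expect_equal(s4$n_total_cells, 2)
  expect_equal(s4$n_reaching, 1)
})

test_that("Rayleigh statistics behave at the concentration extremes", {
  r1 <- rayleigh_test(rep(1.3, 10))
  expect_equal(unname(r1$estimate["mean_resultant_length"]), 1)
  expect_equal(unname(r1$statistic), 10)
  expect_lt(r1$p.value, 1e-4)
  # perfectly symmetric three directions: zero resultant, p = 1
  r0 <- rayleigh_test(c(0, 2 * pi / 3, 4 * pi / 3))
  expect_equal(unname(r0$estimate["mean_resultant_length"]), 0,
               tolerance = 1e-12)
  expect_equal(r0$p.value, 1)
  expect_error(rayleigh_test(c(0, pi)), "at least 3")
  # p is invariant under global rotation
  set.seed(9)
  th <- runif(40, -pi, pi)
  expect_equal(rayleigh_test(th)$p.value,
               rayleigh_test(qpitrack:::wrap_to(th + 1.1, 2 * pi))$p.value,
               tolerance = 1e-12)
})

test_that("Rayleigh test holds its nominal type-I error under uniformity", {
  set.seed(42)
  n <- 60
  reps <- 2000
  rej <- 0L
  for (i in seq_len(reps)) {
    p <- rayleigh_test(runif(n, -pi, pi))$p.value
    if (p < 0.05) rej <- rej + 1L
  }
  rate <- rej / reps
  # 3 MC sigmas around 0.05 for 2000 draws
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("mean-direction CI covers a von Mises drift direction", {
  set.seed(8)
  # wrapped-normal-ish concentrated sample around 0.8
  th <- 0.8 + rnorm(100, 0, 0.5)
  r <- rayleigh_test(th)
  mu <- unname(r$estimate["mean_direction_rad"])
  expect_lt(abs(mu - 0.8), r$conf.int.halfwidth.rad)
  expect_true(is.finite(r$conf.int.halfwidth.rad))
})

test_that("nested ANOVA matches the explicit sums-of-squares oracle", {
  set.seed(3)
  # balanced two populations x 3 movies x 8 cells
  d <- expand.grid(cell = 1:8, movie = 1:3, population = c("A", "B"))
  d$response <- rnorm(nrow(d)) +
    ifelse(d$population == "B", 0.8, 0) +
    rep(rnorm(6, 0, 0.3), each = 8)
  fit <- gradient_component_anova(d)
  ora <- oracle_nested_F(d$response, d$population, d$movie)
  expect_equal(fit$F, ora$F, tolerance = 1e-9)
  expect_equal(fit$df, c(ora$df1, ora$df2))
  expect_equal(fit$p.value, ora$p, tolerance = 1e-9)
  # identical populations: F ~ 0, p ~ 1
  d2 <- d; d2$response <- rep(rnorm(24), 2)
  fit2 <- gradient_component_anova(d2)
  expect_lt(fit2$F, 1e-20)
  expect_gt(fit2$p.value, 0.999)
  # a population with a single movie is refused
  d3 <- d[!(d$population == "B" & d$movie > 1), ]
  expect_error(gradient_component_anova(d3), "stratum")
})

test_that("drifting populations are detected by the hierarchical test", {
  # power simulation: drift 0 vs 5 um/h along +x, 4 movies x 20 cells
  run_rep <- function(seed) {
    resp <- list()
    for (popi in 1:2) for (mi in 1:4) {
      drift_f <- if (popi == 2) 0.25 else 0  # 0.25 * 20 um/h = 5 um/h
      cells <- lapply(1:20, function(i)
        cell_spec(300, Inf, c(200 + (i %% 5) * 20, 200 + (i %/% 5) * 20),
                  speed_um_per_h = 20, persistence_time_min = 30,
                  drift_direction_rad = if (drift_f > 0) 0 else NULL,
                  drift_fraction = drift_f, shape_sigma_um = c(5, 5)))
      sp <- scene_spec(field_size_px = c(300, 300), pixel_size_um = 2,
                       lapse_interval_min = 10, n_frames = 21,
                       cells = cells,
                       rng_seed = seed * 100 + popi * 10 + mi)
      d <- simulate_tracks(sp)$trajectories
      d$track_id <- d$cell
      comp <- displacement_components(d, 0, 10)
      comp$population <- popi; comp$movie <- mi
      resp[[length(resp) + 1]] <- comp
    }
    d <- do.call(rbind, resp)
    d$response <- d$component_um_per_h
    gradient_component_anova(d)$p.value
  }
  ps <- vapply(1:25, run_rep, 0)
  expect_gte(mean(ps < 0.05), 0.9)
})

test_that("the 2x2 chi-square matches closed form, oracle and base R", {
  # independence
  r <- incidence_chi_square(5, 5, 5, 5)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  # metastasis incidence counts: 0/20 vs 9/15
  r2 <- incidence_chi_square(0, 20, 9, 15)
  expect_equal(unname(r2$statistic), 44 * 180^2 / (20 * 24 * 9 * 35),
               tolerance = 1e-12)
  expect_equal(unname(r2$statistic), 9.4286, tolerance = 1e-4)
  expect_equal(r2$p.value, 2.1e-3, tolerance = 0.03)
  expect_lt(r2$p.value, 0.01)
  # numeric-integration CDF oracle
  expect_equal(r2$p.value, oracle_chisq1_p(unname(r2$statistic)),
               tolerance = 1e-8)
  # base-R cross-check (uncorrected Pearson)
  base_r <- suppressWarnings(
    stats::chisq.test(matrix(c(0, 9, 20, 15), 2), correct = FALSE))
  expect_equal(unname(r2$statistic), unname(base_r$statistic),
               tolerance = 1e-12)
  expect_equal(r2$p.value, base_r$p.value, tolerance = 1e-12)
  # Yates correction shrinks the statistic; zero margins error
  expect_lt(unname(incidence_chi_square(0, 20, 9, 15,
                                        yates = TRUE)$statistic),
            unname(r2$statistic))
  expect_error(incidence_chi_square(0, 0, 9, 15), "margin")
})
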
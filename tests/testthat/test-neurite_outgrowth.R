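test_that("track velocity is net displacement over elapsed time", {
  tr <- tibble::tibble(track_id = "a", condition = "permissive",
                       hour = 0:16, axial_position_um = 10 * (0:16))
  expect_equal(track_velocity(tr)$velocity_um_per_hr, 10)
  stall <- tibble::tibble(track_id = "b", condition = "prohibitive",
                          hour = c(0, 8, 16),
                          axial_position_um = c(5, 30, 5))
  expect_equal(track_velocity(stall)$velocity_um_per_hr, 0)
  expect_error(track_velocity(tr[1, ]), "at least 2")
})

test_that("cohort velocities recover the generator means at the study n", {
  sim <- simulate_neurite_dataset(seed = 1)
  vel <- track_velocity(sim$tracks)
  for (cond in c("permissive", "prohibitive")) {
    v <- vel$velocity_um_per_hr[vel$condition == cond]
    target <- c(permissive = 11.4, prohibitive = 2.9)[[cond]]
    sem <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - target), 2 * sem)
  }
})

test_that("outgrowth regression matches deterministic and noisy cohorts", {
  lin <- tibble::tibble(track_id = rep(c("a", "b"), each = 17),
                        condition = "permissive", hour = rep(0:16, 2),
                        axial_position_um = c(10 * (0:16), 12 * (0:16)))
  fit <- outgrowth_regression(lin)
  expect_equal(fit$r_squared, 1.0)
  expect_equal(fit$slope_um_per_hr, 11)

  flat <- tibble::tibble(track_id = "a", condition = "x", hour = 0:5,
                         axial_position_um = rep(40, 6))
  expect_equal(outgrowth_regression(flat)$slope_um_per_hr, 0)

  slopes <- vapply(1:20, function(s) {
    sim <- simulate_neurite_dataset(
      n_tracks_per_condition = c(permissive = 97),
      mean_step_um_per_hr = c(permissive = 11.4),
      step_sd_um_per_hr = c(permissive = 11.4),  # sd = mean step
      seed = s)
    outgrowth_regression(sim$tracks)$slope_um_per_hr
  }, double(1))
  expect_lt(abs(mean(slopes) - 11.4) / 11.4, 0.15)
})

test_that("traversal extent thresholds the profile against background", {
  pos <- seq(0, 900, by = 5)
  full <- tibble::tibble(axial_um = pos, intensity = 100)
  dark <- tibble::tibble(axial_um = pos, intensity = 0)
  # signal spanning the whole channel, thresholded against a dark reference
  expect_equal(traversal_extent(full, 900, reference = dark), 100)
  quarter <- tibble::tibble(axial_um = pos,
                            intensity = ifelse(pos <= 225, 80, 0))
  expect_equal(traversal_extent(quarter, 900), 25)
  none <- tibble::tibble(axial_um = pos, intensity = 0)
  expect_equal(traversal_extent(none, 900), 0)
  expect_error(traversal_extent(full[1:3, ], 900), "background")

  # prohibitive-style simulated profile stalls early
  sim <- simulate_neurite_dataset(
    n_tracks_per_condition = c(prohibitive = 50),
    mean_step_um_per_hr = c(prohibitive = 2.9),
    step_sd_um_per_hr = c(prohibitive = 1),
    hours = 80, seed = 6)
  prof <- sim$profiles
  expect_lte(traversal_extent(prof, 900), 40)
})

test_that("extent never decreases when signal is added outside background", {
  withr::with_seed(23, {
    pos <- seq(0, 900, by = 5)
    for (k in 1:10) {
      base <- tibble::tibble(
        axial_um = pos,
        intensity = pmax(0, 100 - pos / runif(1, 2, 9)))
      e1 <- traversal_extent(base, 900)
      bump <- base
      spot <- sample(which(pos < 0.95 * 900), 1)
      bump$intensity[spot] <- bump$intensity[spot] + runif(1, 10, 200)
      expect_gte(traversal_extent(bump, 900), e1)
    }
  })
})

test_that("success rate counts full crossings", {
  expect_equal(round(success_rate(c(rep(100, 19), rep(40, 8))), 1), 70.4)
  expect_equal(success_rate(rep(0, 12)), 0)
  expect_equal(success_rate(c(3, 50, 99), full_crossing_threshold_pct = 0),
               100)
  expect_error(success_rate(numeric(0)), "no extents")
  withr::with_seed(3, {
    ext <- runif(40, 0, 100)
    shuffled <- sample(ext)
    expect_equal(success_rate(ext), success_rate(shuffled))
    expect_equal(success_rate(ext), 100 * sum(ext >= 95) / 40)
  })
})

test_that("group comparisons separate the study conditions", {
  skip_if_not_installed("multcomp")
  withr::with_seed(12, {
    same <- tibble::tibble(condition = rep(c("a", "b"), each = 30),
                           value = rep(rnorm(30, 5, 1), 2))
  })
  gc_null <- group_comparison(same)
  expect_lt(abs(gc_null$pairwise$t_statistic), 1e-8)
  expect_gte(gc_null$pairwise$p_value, 0.9)

  hits <- vapply(1:20, function(s) {
    sim <- simulate_neurite_dataset(seed = 100 + s)
    vel <- track_velocity(sim$tracks)
    gc <- group_comparison(
      tibble::tibble(condition = vel$condition,
                     value = vel$velocity_um_per_hr))
    gc$pairwise$p_value < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  sim <- simulate_neurite_dataset(
    n_tracks_per_condition = c(permissive = 40, prohibitive = 40,
                               control_straight = 40),
    mean_step_um_per_hr = c(permissive = 11.4, prohibitive = 2.9,
                            control_straight = 11.0),
    step_sd_um_per_hr = c(permissive = 4, prohibitive = 1,
                          control_straight = 4),
    seed = 9)
  vel <- track_velocity(sim$tracks)
  gc <- group_comparison(tibble::tibble(condition = vel$condition,
                                        value = vel$velocity_um_per_hr),
                         control_label = "control_straight")
  expect_equal(sort(gc$dunnett$group), c("permissive", "prohibitive"))
  # single-step adjustment can only raise p-values
  expect_true(all(gc$dunnett$p_adjusted >= gc$dunnett$p_unadjusted - 1e-12))
  expect_error(group_comparison(same, control_label = "zzz"), "control_label")
})

test_that("track and profile tables round-trip through CSV", {
  sim <- simulate_neurite_dataset(
    n_tracks_per_condition = c(permissive = 3), seed = 2)
  f1 <- tempfile(fileext = ".csv")
  write_track_csv(sim$tracks, f1)
  back <- read_track_csv(f1)
  expect_equal(nrow(back), nrow(sim$tracks))
  expect_equal(back$axial_position_um, sim$tracks$axial_position_um)
  f2 <- tempfile(fileext = ".csv")
  write_profile_csv(sim$profiles, f2)
  expect_equal(read_profile_csv(f2)$intensity, sim$profiles$intensity)
})
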
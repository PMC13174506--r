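test_that("channel layouts place electrodes at the pitch grid", {
  ch <- build_channel_layout(910, 17.5, "directional")
  expect_equal(nrow(ch$layout), 53)
  expect_equal(ch$layout$x_um, seq(0, 910, by = 17.5))
  expect_equal(ch$spec$length_um, 910)
  expect_equal(ch$spec$kind, "directional")

  tiny <- build_channel_layout(17.5, 17.5, "straight")
  expect_equal(nrow(tiny$layout), 2)

  ch900 <- build_channel_layout(900, 17.5, "straight")
  expect_equal(nrow(ch900$layout), 52)
  expect_equal(max(ch900$layout$x_um), 892.5)
  expect_equal(ch900$spec$length_um, 892.5)

  expect_error(build_channel_layout(10, 17.5, "straight"), "fewer than 2")
})

test_that("poisson trains are reproducible and have the right mass", {
  ch <- build_channel_layout(910, 17.5, "straight")
  empty <- simulate_poisson_trains(ch$layout, 0, 600, seed = 1)
  expect_equal(nrow(empty), 0)

  one <- electrode_layout(1L, 0, 0)
  st <- simulate_poisson_trains(one, 2, 600, seed = 5)
  ci <- qpois(c(0.005, 0.995), 2 * 600)
  expect_gte(nrow(st), ci[1])
  expect_lte(nrow(st), ci[2])

  a <- simulate_poisson_trains(ch$layout, 2, 60, seed = 11)
  b <- simulate_poisson_trains(ch$layout, 2, 60, seed = 11)
  expect_identical(a$time_s, b$time_s)
  expect_error(simulate_poisson_trains(one, -1, 10), ">= 0")
})

test_that("injected propagation delays are linear in distance", {
  ch <- build_channel_layout(910, 17.5, "straight")
  sp <- inject_propagating_events(ch$layout, ch$spec, 1.0, 10,
                                  total_latency_ms = 1.4)
  mid <- sp[sp$electrode_id == 27L, ]  # electrode at 455 um
  expect_equal(mid$time_s, 1.0007)

  two <- electrode_layout(1:2, x_um = c(0, 650), y_um = 0)
  spec2 <- microchannel_spec("v", "straight", c(0, 0), c(650, 0), 1:2)
  sp2 <- inject_propagating_events(two, spec2, 2.0, 10,
                                   velocity_um_per_ms = 650)
  expect_equal(sp2$time_s[sp2$electrode_id == 2L], 2.001)

  dropped <- inject_propagating_events(ch$layout, ch$spec, c(1, 2), 10,
                                       total_latency_ms = 1.4,
                                       dropout_prob = 1, seed = 3)
  expect_equal(sort(unique(dropped$electrode_id)), 1L)
  expect_equal(nrow(dropped), 2)
})

test_that("rendered recordings have the template trough and noise floor", {
  ch <- build_channel_layout(35, 17.5, "straight")
  st <- spike_table(data.frame(electrode_id = 1L, time_s = 0.5,
                               amplitude_uv = -60), duration_s = 1)
  rec <- render_raw_recording(st, ch$layout, 20000, noise_sd_uv = 0)
  expect_equal(min(rec$signals[1, ]), -60)
  expect_equal(which.min(rec$signals[1, ]), round(0.5 * 20000) + 1)
  expect_equal(max(abs(rec$signals[2, ])), 0)

  silent <- spike_table(data.frame(electrode_id = integer(),
                                   time_s = double(),
                                   amplitude_uv = double()), duration_s = 1.5)
  noisy <- render_raw_recording(silent, ch$layout, 20000, noise_sd_uv = 5,
                                seed = 2)
  rms <- sqrt(mean(noisy$signals[1, ]^2))
  expect_lt(abs(rms - 5) / 5, 0.05)

  # template mass is independent of placement (shift invariance)
  st2 <- spike_table(data.frame(electrode_id = 1L, time_s = 0.25,
                                amplitude_uv = -60), duration_s = 1)
  rec2 <- render_raw_recording(st2, ch$layout, 20000, noise_sd_uv = 0)
  expect_equal(sum(rec2$signals[1, ]), sum(rec$signals[1, ]))
})

test_that("straight datasets are symmetric and directional ones asymmetric", {
  sim <- simulate_channel_dataset(simulation_config(
    kind = "straight", duration_s = 300, proximal_rate_hz = 2, seed = 21))
  qr <- quartile_rates(sim$spikes, axial_map(sim$layout, sim$spec))
  q <- qr$quartile_means$mean_rate_hz
  # symmetric construction: entry and exit quartiles both at ~2 Hz
  se <- sqrt(2 / 300 / 13)
  expect_lt(abs(q[1] - q[4]), 6 * se)

  simd <- simulate_channel_dataset(simulation_config(
    kind = "directional", duration_s = 600, seed = 22))
  gt <- simd$ground_truth
  expect_equal(gt$true_velocity_mm_per_ms, 0.65)
  amap <- axial_map(simd$layout, simd$spec)
  qrd <- quartile_rates(simd$spikes, amap)
  qd <- qrd$quartile_means$mean_rate_hz
  # ground-truth construction: 2.6 Hz entry, 7.7 Hz exit quartile
  expect_lt(abs(qd[1] - 2.6), 4 * sqrt(2.6 / 600 / 13))
  expect_lt(abs(qd[4] - 7.7), 4 * sqrt(7.7 / 600 / 14))
})

test_that("generators are deterministic and conserve events at zero dropout", {
  cfg <- simulation_config(kind = "directional", duration_s = 30, seed = 9)
  a <- simulate_channel_dataset(cfg)
  b <- simulate_channel_dataset(cfg)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
  expect_identical(a$spikes$time_s, b$spikes$time_s)
  expect_equal(nrow(a$ground_truth$events), nrow(a$spikes))
  expect_setequal(unique(a$ground_truth$events$population),
                  c("proximal", "distal"))
})

test_that("neurite generator hits deterministic limits and stated rates", {
  det <- simulate_neurite_dataset(
    n_tracks_per_condition = c(permissive = 10),
    mean_step_um_per_hr = c(permissive = 10),
    step_sd_um_per_hr = c(permissive = 0),
    hours = 16, seed = 1)
  finals <- det$tracks[det$tracks$hour == 16, ]
  expect_true(all(finals$axial_position_um == 160))

  still <- simulate_neurite_dataset(
    n_tracks_per_condition = c(prohibitive = 10),
    mean_step_um_per_hr = c(prohibitive = 0),
    step_sd_um_per_hr = c(prohibitive = 0),
    hours = 16, seed = 1)
  expect_true(all(still$tracks$axial_position_um == 0))
  prof <- still$profiles
  expect_true(all(prof$intensity[prof$axial_um > 0] == 0))
  expect_gt(prof$intensity[prof$axial_um == 0], 0)

  big <- simulate_neurite_dataset(
    n_tracks_per_condition = c(permissive = 400, prohibitive = 400),
    hours = 16, seed = 2)
  vel <- track_velocity(big$tracks)
  means <- tapply(vel$velocity_um_per_hr, vel$condition, mean)
  ratio <- means[["permissive"]] / means[["prohibitive"]]
  expect_lt(abs(ratio - 11.4 / 2.9) / (11.4 / 2.9), 0.10)
})
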
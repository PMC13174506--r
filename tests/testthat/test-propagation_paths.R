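test_that("event pairing honors the closed 1-2 ms window", {
  p <- find_paired_events(0.1, 0.1015)
  expect_equal(p$n_pairs, 1)
  expect_equal(p$pairs$latency_s, 0.0015)
  expect_equal(find_paired_events(0.1, 0.1005)$n_pairs, 0)  # below window
  expect_equal(find_paired_events(0.1, 0.1025)$n_pairs, 0)  # above window
  # both boundaries are included
  expect_equal(find_paired_events(c(0.1, 0.2), c(0.101, 0.202))$pairs$latency_s,
               c(0.001, 0.002))
  # each target used at most once
  p2 <- find_paired_events(c(0.1, 0.1002), 0.1015)
  expect_equal(p2$n_pairs, 1)
  expect_equal(p2$pairs$t_source_s, 0.1)
})

test_that("qualification needs at least 30 paired events", {
  src29 <- (1:29) * 0.1
  expect_false(find_paired_events(src29, src29 + 0.0014)$qualified)
  src30 <- (1:30) * 0.1
  expect_true(find_paired_events(src30, src30 + 0.0014)$qualified)
})

test_that("greedy pairing achieves the maximum-matching pair count", {
  skip_if_not_installed("igraph")
  withr::with_seed(77, {
    for (k in 1:40) {
      ns <- sample(0:20, 1)
      nt <- sample(0:20, 1)
      src <- sort(runif(ns, 0, 0.05))
      tgt <- sort(runif(nt, 0, 0.05))
      got <- find_paired_events(src, tgt)$n_pairs
      want <- pairing_count_oracle(src, tgt, 0.001, 0.002)
      expect_equal(got, want)
      expect_lte(got, min(ns, nt))
    }
  })
})

test_that("co-occurrence counts windows containing candidate events", {
  src <- (1:100) * 0.1
  pairs <- find_paired_events(src, src + 0.0015)
  inside <- src + 0.0007
  expect_equal(cooccurrence_fraction(pairs, inside), 1.0)
  expect_equal(cooccurrence_fraction(pairs, numeric(0)), 0.0)
  expect_equal(cooccurrence_fraction(pairs, inside[1:81]), 0.81)
  # window is closed: an event exactly at t_source counts
  expect_equal(cooccurrence_fraction(pairs, src[1]), 0.01)
})

test_that("intermediary selection applies anchors, strictness, and ties", {
  src <- (1:100) * 0.1
  tgt <- src + 0.0015
  pairs <- find_paired_events(src, tgt, source_electrode = 1L,
                              target_electrode = 99L)

  make_amap <- function(fracs, ids) {
    layout <- electrode_layout(ids, x_um = fracs * 910, y_um = 0)
    axial_map(layout, source_xy_um = c(0, 0), target_xy_um = c(910, 0))
  }
  # sole candidate near the 25% anchor, firing in 95% of windows
  amap <- make_amap(0.26, 5L)
  sp95 <- spike_table(data.frame(electrode_id = 5L,
                                 time_s = src[1:95] + 0.0005,
                                 amplitude_uv = -60), duration_s = 11)
  sel <- select_intermediaries(amap, 5L, pairs, sp95)
  expect_equal(sel$electrode_id[sel$anchor == 0.25], 5L)

  # exactly 80% co-occurrence is rejected (strict inequality)
  sp80 <- spike_table(data.frame(electrode_id = 5L,
                                 time_s = src[1:80] + 0.0005,
                                 amplitude_uv = -60), duration_s = 11)
  expect_equal(nrow(select_intermediaries(amap, 5L, pairs, sp80)), 0)

  # equidistant candidates: smaller electrode id wins
  amap2 <- make_amap(c(0.24, 0.26), c(9L, 4L))
  spikes2 <- spike_table(data.frame(
    electrode_id = rep(c(9L, 4L), each = 100),
    time_s = c(src + 0.0005, src + 0.0006),
    amplitude_uv = -60), duration_s = 11)
  sel2 <- select_intermediaries(amap2, c(9L, 4L), pairs, spikes2)
  expect_equal(sel2$electrode_id[sel2$anchor == 0.25], 4L)
})

test_that("latency traces are linear for noiseless propagation", {
  ch <- build_channel_layout(910, 17.5, "straight")
  src <- (1:100) * 0.1
  sp <- inject_propagating_events(ch$layout, ch$spec, src, 11,
                                  total_latency_ms = 1.4)
  res <- analyze_propagation(sp, ch$layout, ch$spec)
  expect_true(res$qualified)
  mid <- res$trace$median_latency_s[res$trace$axial_um == 455]
  expect_equal(mid, 0.0007)
  expect_true(all(diff(res$trace$axial_um) > 0))
  expect_equal(res$velocity$velocity_mm_per_ms, 0.65, tolerance = 1e-12)
})

test_that("median latencies resist jitter", {
  ch <- build_channel_layout(910, 17.5, "straight")
  src <- (1:200) * 0.05
  sp <- inject_propagating_events(ch$layout, ch$spec, src, 11,
                                  total_latency_ms = 1.4,
                                  jitter_ms = 0.05, seed = 4)
  res <- analyze_propagation(sp, ch$layout, ch$spec)
  expect_true(res$qualified)
  pred <- res$trace$axial_um / 910 * 0.0014
  expect_true(all(abs(res$trace$median_latency_s - pred) <= 5e-5))
})

test_that("velocity fits are exact on collinear traces", {
  tr <- tibble::tibble(electrode_id = 1:2, axial_um = c(0, 910),
                       median_latency_s = c(0, 0.0014))
  expect_equal(fit_velocity(tr)$velocity_mm_per_ms, 0.65)
  for (v in c(0.3, 0.65, 1.0, 2.0)) {  # mm/ms
    ax <- seq(0, 910, length.out = 5)
    tr5 <- tibble::tibble(electrode_id = 1:5, axial_um = ax,
                          median_latency_s = ax / (v * 1000) / 1000)
    expect_equal(fit_velocity(tr5)$velocity_mm_per_ms, v, tolerance = 1e-12)
  }
  flat <- tibble::tibble(electrode_id = 1:2, axial_um = c(0, 910),
                         median_latency_s = c(0.001, 0.001))
  expect_error(fit_velocity(flat), "zero latency spread")
  expect_error(fit_velocity(flat[1, ]), "at least 2")
})

test_that("velocity recovery over a grid is exact without noise, 5% with jitter", {
  ch <- build_channel_layout(910, 17.5, "straight")
  wide <- analysis_config(latency_window_s = c(0.0001, 0.004))
  for (v_mm in c(0.3, 0.65, 1.0, 2.0)) {
    src <- (1:50) * 0.1
    sp <- inject_propagating_events(ch$layout, ch$spec, src, 6,
                                    velocity_um_per_ms = v_mm * 1000)
    res <- analyze_propagation(sp, ch$layout, ch$spec, wide)
    expect_true(res$qualified)
    expect_equal(res$velocity$velocity_mm_per_ms, v_mm, tolerance = 1e-9)
  }
  recovered <- vapply(1:20, function(s) {
    src <- (1:60) * 0.1
    sp <- inject_propagating_events(ch$layout, ch$spec, src, 6.5,
                                    total_latency_ms = 1.4,
                                    jitter_ms = 0.05, seed = s)
    analyze_propagation(sp, ch$layout, ch$spec)$velocity$velocity_mm_per_ms
  }, double(1))
  expect_lt(abs(mean(recovered) - 0.65) / 0.65, 0.05)
})

test_that("forward-injected data yield no reverse-orientation pairs", {
  ch <- build_channel_layout(910, 17.5, "directional")
  src <- (1:100) * 0.1
  sp <- inject_propagating_events(ch$layout, ch$spec, src, 11,
                                  total_latency_ms = 1.4)
  res <- analyze_propagation(sp, ch$layout, ch$spec, direction = "backward")
  expect_equal(res$pairs$n_pairs, 0)
})

test_that("channel classification separates the three study conditions", {
  simd <- simulate_channel_dataset(simulation_config(
    kind = "directional", duration_s = 120, seed = 31))
  repd <- classify_direction(simd$spikes, simd$layout, simd$spec)
  expect_equal(repd$classification, "forward_only")
  expect_gt(repd$forward$velocity$velocity_mm_per_ms, 0)

  sims <- simulate_channel_dataset(simulation_config(
    kind = "straight", duration_s = 120, proximal_rate_hz = 2.6, seed = 32))
  reps <- classify_direction(sims$spikes, sims$layout, sims$spec)
  expect_equal(reps$classification, "both")

  ch <- build_channel_layout(910, 17.5, "straight")
  null_sp <- simulate_poisson_trains(ch$layout, 2, 60, seed = 33)
  repn <- classify_direction(null_sp, ch$layout, ch$spec)
  expect_equal(repn$classification, "none")
  td <- tidy(repn)
  expect_lt(td$forward_pairs, 30)
  expect_lt(td$backward_pairs, 30)
})
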
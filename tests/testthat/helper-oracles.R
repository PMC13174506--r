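# Independent oracles used to cross-check the implementation.

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
mw_exact_oracle <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Maximum number of source-target pairs with latency in [lo, hi], each event
# used once: maximum bipartite matching on the admissibility graph.
pairing_count_oracle <- function(source_times, target_times, lo, hi) {
  ns <- length(source_times)
  nt <- length(target_times)
  if (ns == 0 || nt == 0) return(0L)
  edges <- integer(0)
  for (i in seq_len(ns)) {
    for (j in seq_len(nt)) {
      lat <- target_times[j] - source_times[i]
      if (lat >= lo && lat <= hi) edges <- c(edges, i, ns + j)
    }
  }
  if (length(edges) == 0) return(0L)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, ns), rep(TRUE, nt)),
                                    edges = edges)
  igraph::max_bipartite_match(g)$matching_size
}

# Exhaustive per-sample threshold scan: contiguous supra-threshold runs,
# largest-|v| sample per run.
detect_spikes_oracle <- function(trace, sampling_rate_hz, threshold_uv) {
  events <- list()
  in_run <- FALSE
  best_idx <- NA_integer_
  for (i in seq_along(trace)) {
    if (abs(trace[i]) > threshold_uv) {
      if (!in_run || abs(trace[i]) > abs(trace[best_idx])) best_idx <- i
      in_run <- TRUE
    } else if (in_run) {
      events[[length(events) + 1]] <- best_idx
      in_run <- FALSE
    }
  }
  if (in_run) events[[length(events) + 1]] <- best_idx
  idx <- unlist(events) %||% integer(0)
  data.frame(time_s = (idx - 1) / sampling_rate_hz,
             amplitude_uv = trace[idx])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic uniform spike table: each electrode fires `n_events` evenly
# spaced events over the duration.
uniform_spikes <- function(layout, n_events, duration_s) {
  df <- do.call(rbind, lapply(layout$electrode_id, function(id) {
    data.frame(electrode_id = id,
               time_s = seq(0, duration_s * (1 - 1 / n_events),
                            length.out = n_events),
               amplitude_uv = -60)
  }))
  spike_table(df, duration_s = duration_s)
}

random_spike_table <- function(n, duration_s = 10, n_electrodes = 4) {
  df <- data.frame(
    electrode_id = sample.int(n_electrodes, n, replace = TRUE),
    time_s = runif(n, 0, duration_s),
    amplitude_uv = -runif(n, 20, 90)
  )
  spike_table(df, duration_s = duration_s)
}
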
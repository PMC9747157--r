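# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive per-sample loops, not the package's code paths.

# Per-sample scan for threshold-crossing runs in a trace.
naive_detect <- function(trace, lags_ms, mu, sdev, fs, k_sd = 3,
                         min_duration_ms = 1, search = c(2, 70)) {
  dt <- 1000 / fs
  min_len <- ceiling(min_duration_ms * fs / 1000)
  eligible <- lags_ms >= search[1] & lags_ms < search[2] &
    !(lags_ms >= 0 & lags_ms < 2)
  out <- list()
  for (side in c("Facilitation", "Suppression")) {
    thr <- if (side == "Facilitation") mu + k_sd * sdev else mu - k_sd * sdev
    i <- 1L
    n <- length(trace)
    while (i <= n) {
      hit <- eligible[i] && (if (side == "Facilitation") trace[i] > thr else trace[i] < thr)
      if (!hit) { i <- i + 1L; next }
      j <- i
      while (j < n && eligible[j + 1L] &&
             (if (side == "Facilitation") trace[j + 1L] > thr else trace[j + 1L] < thr))
        j <- j + 1L
      if (j - i + 1L >= min_len) {
        area <- 0
        for (k in i:j) area <- area + abs(trace[k] - thr) * dt
        out[[length(out) + 1L]] <- data.frame(
          effect_type = side, onset_ms = lags_ms[i],
          duration_ms = (j - i + 1L) * dt, area_uv_ms = area,
          threshold_uv = thr)
      }
      i <- j + 1L
    }
  }
  if (!length(out))
    return(data.frame(effect_type = character(0), onset_ms = numeric(0),
                      duration_ms = numeric(0), area_uv_ms = numeric(0),
                      threshold_uv = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$onset_ms, -res$area_uv_ms), , drop = FALSE]
}

# Vector-summation PD by explicit loop.
naive_pd <- function(m, angles_deg) {
  Rx <- 0; Ry <- 0
  for (i in seq_along(m)) {
    Rx <- Rx + m[i] * cos(angles_deg[i] * pi / 180)
    Ry <- Ry + m[i] * sin(angles_deg[i] * pi / 180)
  }
  (atan2(Ry, Rx) * 180 / pi) %% 360
}

# Circular median by exhaustive candidate search.
naive_circular_median <- function(a) {
  a <- a %% 360
  circ_dist <- function(x, y) {
    d <- abs(x - y) %% 360
    min(d, 360 - d)
  }
  cost <- sapply(a, function(cand) sum(sapply(a, circ_dist, y = cand)))
  a[which.min(cost)]
}

# A tiny hand-built session: one muscle, constant EMG, simple event list.
tiny_session <- function(fs = 2000, dur_s = 4, triggers = c(1, 1.5, 2, 2.5),
                         events = NULL) {
  T <- dur_s * fs
  if (is.null(events))
    events <- data.frame(
      state = c("center_hold", "movement", "peripheral_hold"),
      target_angle_deg = c(NA, NA, 90),
      start_s = c(0.0, 0.9, 1.3),
      end_s = c(0.9, 1.3, 3.0))
  session_recording(
    sampling_rate_hz = fs,
    emg = list(m1 = rep(10, T)),
    torque_x = rep(0.1, T), torque_y = rep(0, T),
    trigger_times_s = triggers, events = events)
}

# Small generator config used across tests (quick to simulate).
quick_cfg <- function(..., n_trials_per_target = 6, seed = 42) {
  generator_config(n_trials_per_target = n_trials_per_target, seed = seed, ...)
}
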
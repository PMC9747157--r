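#' Synthetic-session generator configuration
#'
#' Defines a simulated experiment: task schedule (eight peripheral targets,
#' timed hold periods, fixed inter-stimulus interval), cosine-tuned
#' rectified-Gaussian EMG per muscle, a stimulus-effect model (additive
#' raised-cosine facilitation with background-dependent amplitude and a
#' multiplicative raised-cosine suppression dip), and an EMG-driven torque
#' model. The generated statistics have closed-form expectations
#' ([expected_background_level()], [expected_pste_area()]) used as oracles
#' in recovery tests.
#'
#' EMG model: during holds, `EMG_m(t) = |eps(t)| * b_m(t)` with
#' `eps ~ N(0,1)` i.i.d. and `b_m = b0 * (1 + d*cos(theta - pd))` during a
#' peripheral hold toward `theta`; center holds (and rest) use the floor
#' `b0 * (1 - d)`. Each stimulus adds a facilitation bump of peak amplitude
#' `min(g0 + g1 * b_m, cap)` and scales the EMG by `1 - s * w(t)` over the
#' suppression window (`w` a raised cosine reaching 1 mid-window).
#'
#' Torque model: `torque(t) = sum_m gain_m * lowpass(EMG_m) * pull_m +
#' noise`, with a first-order low-pass (default time constant 10 ms)
#' standing in for musculotendon dynamics.
#'
#' @param n_trials_per_target Completed trials per peripheral target.
#' @param muscles Data frame with one row per muscle: `name`, `pd_deg`
#'   (preferred direction of the background tuning), `b0` (baseline scale,
#'   uV), `d` (tuning depth in `[0,1]`), `pull_x`, `pull_y` (unit pull
#'   vector used by the torque model), `torque_gain` (N·m per uV).
#' @param g0,g1 Additive facilitation amplitude: intercept (uV) and
#'   dimensionless gain on the instantaneous background scale.
#' @param facilitation_cap Peak-amplitude cap (uV) emulating a saturating
#'   recruitment regime; default `Inf` (linear gain).
#' @param facil_latency_ms,facil_width_ms Facilitation bump onset and width.
#' @param s Suppression depth in `[0,1]` (0 disables suppression).
#' @param supp_latency_ms,supp_width_ms Suppression dip onset and width.
#' @param hold_center_s,hold_peripheral_s,movement_s,intertrial_s Task
#'   epoch durations (s).
#' @param isi_ms Inter-stimulus interval (ms); stimulation runs continuously
#'   through all task states.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param torque_noise_sd Additive white torque noise (N·m).
#' @param torque_tau_ms Low-pass time constant of the torque model (ms).
#' @param current_intensity_label Free-form label stored in metadata.
#' @param seed Integer seed; the whole session is a deterministic function
#'   of the config including the seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_trials_per_target = 10,
                             muscles = default_muscles(),
                             g0 = 0, g1 = 0.8, facilitation_cap = Inf,
                             facil_latency_ms = 6, facil_width_ms = 4,
                             s = 0, supp_latency_ms = 15, supp_width_ms = 10,
                             hold_center_s = 0.8, hold_peripheral_s = 0.75,
                             movement_s = 0.3, intertrial_s = 0.2,
                             isi_ms = 197, sampling_rate_hz = 2000,
                             torque_noise_sd = 0.002, torque_tau_ms = 10,
                             current_intensity_label = "default",
                             seed = 1L) {
  muscles <- as.data.frame(muscles)
  cfg <- structure(as.list(environment()), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Default muscle table: two antagonist wrist muscles
#' @return Muscle data frame accepted by [generator_config()].
#' @export
default_muscles <- function() {
  data.frame(name = c("ECR", "FCR"),
             pd_deg = c(0, 180),
             b0 = c(20, 20),
             d = c(0.5, 0.5),
             pull_x = c(1, -1), pull_y = c(0, 0),
             torque_gain = c(0.01, 0.01),
             stringsAsFactors = FALSE)
}

validate_generator_config <- function(cfg) {
  m <- cfg$muscles
  need <- c("name", "pd_deg", "b0", "d", "pull_x", "pull_y", "torque_gain")
  if (!all(need %in% names(m)))
    stop("generator config error: muscles table missing columns ",
         paste(setdiff(need, names(m)), collapse = ", "))
  if (anyDuplicated(m$name)) stop("generator config error: duplicate muscle names")
  if (any(m$b0 < 0) || any(m$d < 0 | m$d > 1))
    stop("generator config error: require b0 >= 0 and d in [0,1]")
  if (cfg$s < 0 || cfg$s > 1) stop("generator config error: s must be in [0,1]")
  if (cfg$facil_width_ms <= 0 || cfg$supp_width_ms <= 0)
    stop("generator config error: kernel widths must be positive")
  if (cfg$facil_latency_ms < 2 || cfg$supp_latency_ms < 2)
    stop("generator config error: effect latencies must be >= 2 ms (artifact mask)")
  if (cfg$n_trials_per_target < 1) stop("generator config error: need >= 1 trial per target")
  invisible(cfg)
}

# Raised-cosine bump on [0, width), peak 1 at midpoint.
raised_cosine <- function(t_ms, width_ms) {
  w <- numeric(length(t_ms))
  inb <- t_ms >= 0 & t_ms < width_ms
  w[inb] <- 0.5 * (1 - cos(2 * pi * t_ms[inb] / width_ms))
  w
}

# Build the trial schedule: events table plus per-sample background scale
# (per muscle) and the per-sample target angle (NA outside peripheral holds).
build_schedule <- function(cfg) {
  n_tr <- cfg$n_trials_per_target * 8L
  order_idx <- unlist(lapply(seq_len(cfg$n_trials_per_target),
                             function(i) sample(TARGET_ANGLES)))
  trial_len <- cfg$hold_center_s + cfg$movement_s + cfg$hold_peripheral_s +
    cfg$movement_s + cfg$intertrial_s
  starts <- (seq_len(n_tr) - 1) * trial_len
  ev <- do.call(rbind, lapply(seq_len(n_tr), function(i) {
    t0 <- starts[i]
    data.frame(
      state = c("center_hold", "movement", "peripheral_hold", "movement", "intertrial"),
      target_angle_deg = c(NA, NA, order_idx[i], NA, NA),
      start_s = t0 + cumsum(c(0, cfg$hold_center_s, cfg$movement_s,
                              cfg$hold_peripheral_s, cfg$movement_s)),
      end_s = t0 + cumsum(c(cfg$hold_center_s, cfg$movement_s,
                            cfg$hold_peripheral_s, cfg$movement_s,
                            cfg$intertrial_s)),
      stringsAsFactors = FALSE)
  }))
  list(events = ev, targets = order_idx, duration_s = n_tr * trial_len)
}

# Per-sample background scale b_m(t) for one muscle, given the schedule.
# Peripheral hold: b0*(1 + d*cos(theta - pd)); elsewhere the b0*(1-d) floor,
# with linear ramps across movement epochs.
background_scale <- function(cfg, mrow, ev, T) {
  fs <- cfg$sampling_rate_hz
  floor_b <- mrow$b0 * (1 - mrow$d)
  b <- rep(floor_b, T)
  ph <- which(ev$state == "peripheral_hold")
  for (i in ph) {
    lev <- mrow$b0 * (1 + mrow$d * cospi((ev$target_angle_deg[i] - mrow$pd_deg) / 180))
    i0 <- floor(ev$start_s[i] * fs) + 1L
    i1 <- min(ceiling(ev$end_s[i] * fs), T)
    b[i0:i1] <- lev
    # ramps over the flanking movement epochs
    up0 <- floor((ev$start_s[i] - cfg$movement_s) * fs) + 1L
    if (up0 >= 1 && i0 > up0)
      b[up0:(i0 - 1L)] <- floor_b + (lev - floor_b) * seq(0, 1, length.out = i0 - up0)
    dn1 <- min(ceiling((ev$end_s[i] + cfg$movement_s) * fs), T)
    if (dn1 > i1)
      b[(i1 + 1L):dn1] <- lev + (floor_b - lev) * seq(0, 1, length.out = dn1 - i1)
  }
  b
}

#' Generate a synthetic session with known ground truth
#'
#' Deterministic under `cfg$seed`: all random draws come from one seeded
#' stream consumed in a fixed order, so identical configs give
#' byte-identical sessions.
#'
#' @param cfg A [generator_config()].
#' @return List with elements `session` (a [session_recording()]) and
#'   `truth` (per-muscle true preferred directions, expected background and
#'   effect areas per target, true onset latencies; per-target injected
#'   evoked-torque direction and magnitude).
#' @export
generate_session <- function(cfg) {
  validate_generator_config(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  fs <- cfg$sampling_rate_hz
  sch <- build_schedule(cfg)
  T <- round(sch$duration_s * fs)
  trig <- seq(0.1, sch$duration_s - 0.2, by = cfg$isi_ms / 1000)

  # facilitation/suppression kernels on the sample grid
  fk_len <- ceiling(cfg$facil_width_ms / 1000 * fs)
  fk <- raised_cosine((seq_len(fk_len) - 1) / fs * 1000, cfg$facil_width_ms)
  sk_len <- ceiling(cfg$supp_width_ms / 1000 * fs)
  sk <- raised_cosine((seq_len(sk_len) - 1) / fs * 1000, cfg$supp_width_ms)
  trig_idx <- round(trig * fs) + 1L
  fac_at <- trig_idx + round(cfg$facil_latency_ms / 1000 * fs)
  sup_at <- trig_idx + round(cfg$supp_latency_ms / 1000 * fs)

  emg <- vector("list", nrow(cfg$muscles))
  names(emg) <- cfg$muscles$name
  tq_x <- numeric(T); tq_y <- numeric(T)
  alpha <- exp(-1000 / (cfg$torque_tau_ms * fs))
  for (j in seq_len(nrow(cfg$muscles))) {
    mrow <- cfg$muscles[j, ]
    b <- background_scale(cfg, mrow, sch$events, T)
    x <- abs(stats::rnorm(T)) * b
    if (cfg$s > 0) {
      keep <- sup_at + sk_len - 1L <= T
      ii <- rep(sup_at[keep], each = sk_len) + (seq_len(sk_len) - 1L)
      x[ii] <- x[ii] * (1 - cfg$s * rep(sk, sum(keep)))
    }
    if (cfg$g0 > 0 || cfg$g1 > 0) {
      keep <- fac_at + fk_len - 1L <= T
      amp <- pmin(cfg$g0 + cfg$g1 * b[trig_idx[keep]], cfg$facilitation_cap)
      ii <- rep(fac_at[keep], each = fk_len) + (seq_len(fk_len) - 1L)
      x[ii] <- x[ii] + rep(amp, each = fk_len) * rep(fk, sum(keep))
    }
    emg[[j]] <- x
    sm <- as.numeric(stats::filter(x * (1 - alpha), alpha, method = "recursive"))
    tq_x <- tq_x + mrow$torque_gain * sm * mrow$pull_x
    tq_y <- tq_y + mrow$torque_gain * sm * mrow$pull_y
  }
  tq_x <- tq_x + stats::rnorm(T, sd = cfg$torque_noise_sd)
  tq_y <- tq_y + stats::rnorm(T, sd = cfg$torque_noise_sd)

  rec <- session_recording(
    sampling_rate_hz = fs, emg = emg,
    torque_x = tq_x, torque_y = tq_y,
    trigger_times_s = trig, events = sch$events,
    metadata = list(generator = "stimtune synthetic", seed = cfg$seed,
                    current_intensity_label = cfg$current_intensity_label))
  list(session = rec, truth = ground_truth(cfg))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Ground truth implied by a generator config
#'
#' @param cfg A [generator_config()].
#' @return List: per-muscle true PD, expected background per target,
#'   expected facilitation/suppression areas per target, true onset
#'   latencies; per-target evoked-torque direction and magnitude.
#' @export
ground_truth <- function(cfg) {
  per_muscle <- lapply(seq_len(nrow(cfg$muscles)), function(j) {
    m <- cfg$muscles[j, ]
    list(name = m$name, pd_deg = m$pd_deg,
         background_uv = vapply(TARGET_ANGLES, function(a)
           expected_background_level(cfg, m$name, a), numeric(1)),
         facilitation_area = vapply(TARGET_ANGLES, function(a)
           expected_pste_area(cfg, m$name, a)["facilitation"], numeric(1)),
         suppression_area = vapply(TARGET_ANGLES, function(a)
           expected_pste_area(cfg, m$name, a)["suppression"], numeric(1)),
         facil_onset_ms = cfg$facil_latency_ms,
         supp_onset_ms = cfg$supp_latency_ms)
  })
  names(per_muscle) <- cfg$muscles$name
  tq <- lapply(TARGET_ANGLES, function(a) expected_evoked_torque(cfg, a))
  names(tq) <- as.character(TARGET_ANGLES)
  list(seed = cfg$seed, muscles = per_muscle, evoked_torque = tq,
       target_angles_deg = TARGET_ANGLES)
}

#' Expected background EMG level
#'
#' Closed form for the mean rectified EMG during a peripheral hold:
#' `sqrt(2/pi) * b0 * (1 + d*cos(theta - pd))`, since `E|N(0,1)| =
#' sqrt(2/pi)`. `target_angle = "center"` returns the center-hold floor
#' `sqrt(2/pi) * b0 * (1 - d)`.
#'
#' @param cfg A [generator_config()].
#' @param muscle Muscle name.
#' @param target_angle Target angle in degrees, or `"center"`.
#' @return Expected background in uV.
#' @export
expected_background_level <- function(cfg, muscle, target_angle) {
  j <- match(muscle, cfg$muscles$name)
  if (is.na(j)) stop("unknown muscle: ", muscle)
  m <- cfg$muscles[j, ]
  b <- if (identical(target_angle, "center")) m$b0 * (1 - m$d)
  else m$b0 * (1 + m$d * cospi((as.numeric(target_angle) - m$pd_deg) / 180))
  sqrt(2 / pi) * b
}

# Expected per-lag SD of the averaged trace baseline: the StTA of n sweeps
# of |N(0,1)|*b has per-lag SD b*sqrt(1 - 2/pi)/sqrt(n).
expected_trace_sd <- function(b, n_triggers) {
  if (!is.finite(n_triggers)) return(0)
  b * sqrt(1 - 2 / pi) / sqrt(n_triggers)
}

#' Expected post-stimulus-effect area
#'
#' Analytic expectation of the detected area for the injected kernels,
#' measured the way the detector measures it: the part of the mean-trace
#' deviation exceeding the 3 SD detection bound, summed on the sampling
#' grid. For facilitation the mean trace rises by `A * w(t)` above the
#' baseline mean (`A = min(g0 + g1*b, cap)`, `w` the raised cosine); for
#' suppression it falls by `mu * s * w(t)` (`mu = sqrt(2/pi)*b`). With
#' `n_triggers` finite, the baseline SD of an n-sweep average,
#' `b*sqrt(1-2/pi)/sqrt(n)`, sets the 3 SD bound; with `n_triggers = Inf`
#' (default) the bound is zero and the areas are the full kernel areas.
#'
#' @inheritParams expected_background_level
#' @param n_triggers Number of sweeps entering the average (affects the
#'   detection bound); `Inf` for the ideal noiseless area.
#' @param k_sd Detection threshold in baseline SDs (default 3).
#' @return Named numeric vector `c(facilitation=, suppression=)` in uV·ms.
#' @export
expected_pste_area <- function(cfg, muscle, target_angle, n_triggers = Inf,
                               k_sd = 3) {
  j <- match(muscle, cfg$muscles$name)
  if (is.na(j)) stop("unknown muscle: ", muscle)
  m <- cfg$muscles[j, ]
  b <- if (identical(target_angle, "center")) m$b0 * (1 - m$d)
  else m$b0 * (1 + m$d * cospi((as.numeric(target_angle) - m$pd_deg) / 180))
  mu <- sqrt(2 / pi) * b
  thr <- k_sd * expected_trace_sd(b, n_triggers)
  fs <- cfg$sampling_rate_hz
  dt_ms <- 1000 / fs
  fA <- if (cfg$g0 > 0 || cfg$g1 > 0) min(cfg$g0 + cfg$g1 * b, cfg$facilitation_cap) else 0
  f_lag <- seq(0, cfg$facil_width_ms, by = dt_ms)
  fac <- sum(pmax(0, fA * raised_cosine(f_lag, cfg$facil_width_ms) - thr)) * dt_ms
  s_lag <- seq(0, cfg$supp_width_ms, by = dt_ms)
  sup <- sum(pmax(0, mu * cfg$s * raised_cosine(s_lag, cfg$supp_width_ms) - thr)) * dt_ms
  c(facilitation = fac, suppression = sup)
}

#' Expected detected onset latency of the injected effects
#'
#' The detector reports the first sample-grid lag whose mean trace crosses
#' the `k_sd` bound. A raised-cosine kernel is exactly zero at its nominal
#' latency, so the expected detected onset is the first grid lag after the
#' analytic threshold crossing, not the kernel start. Returned per effect
#' type; `NA` when the kernel never crosses the bound.
#'
#' @inheritParams expected_pste_area
#' @return Named numeric vector `c(facilitation=, suppression=)` in ms.
#' @export
expected_pste_onset <- function(cfg, muscle, target_angle, n_triggers = Inf,
                                k_sd = 3) {
  j <- match(muscle, cfg$muscles$name)
  if (is.na(j)) stop("unknown muscle: ", muscle)
  m <- cfg$muscles[j, ]
  b <- if (identical(target_angle, "center")) m$b0 * (1 - m$d)
  else m$b0 * (1 + m$d * cospi((as.numeric(target_angle) - m$pd_deg) / 180))
  mu <- sqrt(2 / pi) * b
  thr <- k_sd * expected_trace_sd(b, n_triggers)
  dt_ms <- 1000 / cfg$sampling_rate_hz
  first_cross <- function(latency, width, peak) {
    if (peak <= thr) return(NA_real_)
    lag <- seq(0, width, by = dt_ms)
    i <- which(peak * raised_cosine(lag, width) > thr)[1]
    if (is.na(i)) NA_real_ else latency + lag[i]
  }
  fA <- if (cfg$g0 > 0 || cfg$g1 > 0) min(cfg$g0 + cfg$g1 * b, cfg$facilitation_cap) else 0
  c(facilitation = first_cross(cfg$facil_latency_ms, cfg$facil_width_ms, fA),
    suppression = first_cross(cfg$supp_latency_ms, cfg$supp_width_ms, mu * cfg$s))
}

#' Expected evoked-torque vector for one target
#'
#' Deterministic mean torque response to one stimulus: the facilitation
#' bumps of all muscles, scaled by their amplitudes at this target, passed
#' through the torque model's first-order low-pass and summed along the
#' pull vectors. Direction is the angle of the summed pull; magnitude the
#' peak excursion of the filtered bump.
#'
#' @inheritParams expected_background_level
#' @return List `direction_deg`, `magnitude_nm`, `peak_lag_ms`.
#' @export
expected_evoked_torque <- function(cfg, target_angle) {
  fs <- cfg$sampling_rate_hz
  v <- c(0, 0)
  for (j in seq_len(nrow(cfg$muscles))) {
    m <- cfg$muscles[j, ]
    b <- m$b0 * (1 + m$d * cospi((as.numeric(target_angle) - m$pd_deg) / 180))
    A <- if (cfg$g0 > 0 || cfg$g1 > 0) min(cfg$g0 + cfg$g1 * b, cfg$facilitation_cap) else 0
    v <- v + m$torque_gain * A * c(m$pull_x, m$pull_y)
  }
  n <- round(0.15 * fs)
  bump <- raised_cosine((seq_len(n) - 1) / fs * 1000 - cfg$facil_latency_ms,
                        cfg$facil_width_ms)
  alpha <- exp(-1000 / (cfg$torque_tau_ms * fs))
  sm <- as.numeric(stats::filter(bump * (1 - alpha), alpha, method = "recursive"))
  mag <- sqrt(sum(v^2)) * max(sm)
  dir <- if (mag > 0) (atan2(v[2], v[1]) * 180 / pi) %% 360 else NA_real_
  list(direction_deg = dir, magnitude_nm = mag,
       peak_lag_ms = (which.max(sm) - 1) / fs * 1000)
}
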
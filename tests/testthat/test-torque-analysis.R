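test_that("torque StTA covers 360 samples at 2 kHz and averages correctly", {
  rec <- tiny_session(dur_s = 4, triggers = c(1.5, 1.8, 2.1))
  ev <- data.frame(state = "peripheral_hold", target_angle_deg = 0,
                   start_s = 1, end_s = 3)
  rec$events <- ev
  asg <- assign_triggers(rec, post_window_ms = 150)
  st <- compute_torque_stta(rec, asg, "0")
  expect_length(st$trace_x, 360)
  expect_length(st$trace_y, 360)
  expect_true(all(st$trace_x == 0.1))  # constant torque -> flat trace
  expect_equal(st$lags_ms[1], -30)
  expect_equal(st$lags_ms[360], 149.5)
  expect_error(compute_torque_stta(rec, asg, "90"), "no assigned triggers")
})

test_that("detrending removes a pure linear trend exactly (order 1 selected)", {
  st <- structure(list(trace_x = 3 + 0.5 * (1:360), trace_y = -2 + 0.1 * (1:360),
                       lags_ms = -30 + (0:359) * 0.5, n_triggers = 100,
                       fs = 2000, hold_state = "0", detrended = FALSE),
                  class = "torque_stta")
  out <- detrend_stta(st)
  expect_equal(out$order_x, 1)
  expect_equal(out$order_y, 1)
  expect_lt(max(abs(out$trace_x)), 1e-8)
  expect_lt(max(abs(out$trace_y)), 1e-8)
})

test_that("a cubic trend plus pulse: the pulse survives detrending within 5%", {
  lags <- -30 + (0:359) * 0.5
  t <- lags / 1000
  trend <- 0.05 + 0.8 * t - 30 * t^2 + 120 * t^3
  pulse <- 0.02 * exp(-((lags - 40) / 4)^2)
  st <- structure(list(trace_x = trend + pulse, trace_y = trend,
                       lags_ms = lags, n_triggers = 100, fs = 2000,
                       hold_state = "0", detrended = FALSE),
                  class = "torque_stta")
  out <- detrend_stta(st)
  peak <- max(out$trace_x[lags >= 30 & lags <= 50])
  expect_lt(abs(peak - 0.02) / 0.02, 0.05)
  # noiseless pulse direction unchanged by more than 5 deg when the fit
  # window excludes the response
  st2 <- st
  st2$trace_y <- trend + pulse  # 45-degree pulse
  out2 <- detrend_stta(st2, fit_window = "baseline")
  sel <- lags >= 0
  dx <- out2$trace_x[sel] - out2$baseline_mean_x
  dy <- out2$trace_y[sel] - out2$baseline_mean_y
  i <- which.max(dx^2 + dy^2)
  expect_lt(abs(wrap_angle(atan2(dy[i], dx[i]) * 180 / pi - 45)), 5)
})

test_that("white-noise traces select order 1 in at least 80% of cases", {
  set.seed(33)
  lags <- -30 + (0:359) * 0.5
  orders <- replicate(400, {
    st <- structure(list(trace_x = rnorm(360), trace_y = rnorm(360),
                         lags_ms = lags, n_triggers = 10, fs = 2000,
                         hold_state = "0", detrended = FALSE),
                    class = "torque_stta")
    detrend_stta(st)$order_x
  })
  expect_gte(mean(orders == 1), 0.8)
})

test_that("evoked-torque detection: farthest point, boundary, and null case", {
  lags <- -30 + (0:359) * 0.5
  mk <- function(x, y, sdx = 0.01, sdy = 0.01) {
    structure(list(trace_x = x, trace_y = y, lags_ms = lags, n_triggers = 50,
                   fs = 2000, hold_state = "90", detrended = TRUE,
                   order_x = 1, order_y = 1,
                   baseline_mean_x = 0, baseline_sd_x = sdx,
                   baseline_mean_y = 0, baseline_sd_y = sdy),
              class = "torque_stta")
  }
  # flat residual: not significant, no vector
  ev <- detect_evoked_torque(mk(rep(0, 360), rep(0, 360)))
  expect_false(ev$significant)
  expect_true(is.na(ev$magnitude_nm))
  # excursion to (0.15, -0.15): magnitude ~0.2121 at 315 deg
  x <- rep(0, 360); y <- rep(0, 360)
  x[lags >= 30 & lags < 40] <- 0.15
  y[lags >= 30 & lags < 40] <- -0.15
  ev <- detect_evoked_torque(mk(x, y))
  expect_true(ev$significant)
  expect_equal(ev$magnitude_nm, sqrt(2) * 0.15, tolerance = 1e-9)
  expect_equal(ev$direction_deg, 315)
  expect_equal(ev$time_ms, 30)
  # exactly 10 sigma on one axis: significant (>= convention)
  x2 <- rep(0, 360); x2[200] <- 0.1
  ev2 <- detect_evoked_torque(mk(x2, rep(0, 360)))
  expect_true(ev2$significant)
  # 9.99 sigma: not significant
  x3 <- rep(0, 360); x3[200] <- 0.0999
  expect_false(detect_evoked_torque(mk(x3, rep(0, 360)))$significant)
  # pre-trigger excursions are outside the search window
  x4 <- rep(0, 360); x4[10] <- 1
  expect_false(detect_evoked_torque(mk(x4, rep(0, 360)))$significant)
  expect_error(detect_evoked_torque(mk(x, y, sdx = 0)), "degenerate")
})

test_that("evoked direction is equivariant under rotation of the torque frame", {
  lags <- -30 + (0:359) * 0.5
  set.seed(44)
  base_x <- rnorm(360, sd = 0.001); base_y <- rnorm(360, sd = 0.001)
  base_x[150:170] <- base_x[150:170] + 0.2
  rot <- function(x, y, th) list(x = x * cos(th) - y * sin(th),
                                 y = x * sin(th) + y * cos(th))
  mk <- function(x, y) {
    st <- structure(list(trace_x = x, trace_y = y, lags_ms = lags,
                         n_triggers = 50, fs = 2000, hold_state = "0",
                         detrended = FALSE), class = "torque_stta")
    detect_evoked_torque(detrend_stta(st))
  }
  d0 <- mk(base_x, base_y)$direction_deg
  for (th_deg in c(30, 90, 200)) {
    r <- rot(base_x, base_y, th_deg * pi / 180)
    d <- mk(r$x, r$y)$direction_deg
    expect_lt(abs(wrap_angle(d - d0 - th_deg)), 1)
  }
})

test_that("normalized torque direction wraps the voluntary-direction difference", {
  expect_equal(normalized_torque_direction(315, 90), -135)
  expect_equal(normalized_torque_direction(90, 90), 0)
  expect_error(normalized_torque_direction(NA, 90), "undefined")
})

test_that("injected torque responses are recovered per target from a session", {
  mus <- data.frame(name = paste0("m", 1:4),
                    pd_deg = c(0, 90, 180, 270), b0 = 20, d = 0.8,
                    pull_x = cospi(c(0, 90, 180, 270) / 180),
                    pull_y = sinpi(c(0, 90, 180, 270) / 180),
                    torque_gain = 0.004)
  cfg <- quick_cfg(muscles = mus, n_trials_per_target = 20, g0 = 0, g1 = 2.5,
                   s = 0, torque_noise_sd = 0.001)
  g <- generate_session(cfg)
  asg <- assign_triggers(g$session, post_window_ms = 150)
  for (a in c("0", "135")) {
    st <- detrend_stta(compute_torque_stta(g$session, asg, a))
    ev <- detect_evoked_torque(st)
    expect_true(ev$significant)
    truth <- g$truth$evoked_torque[[a]]
    expect_lt(abs(wrap_angle(ev$direction_deg - truth$direction_deg)), 10)
    expect_lt(abs(ev$magnitude_nm - truth$magnitude_nm) / truth$magnitude_nm, 0.25)
  }
})
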